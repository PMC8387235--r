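#' Quality-control a spike-table
#'
#' Applies the two artefact rules used for extracellular recordings in this
#' pipeline: spikes detected near-simultaneously (within a coincidence
#' window) on many channels are treated as electrical artefacts and removed,
#' and within each unit the later spike of any pair violating the refractory
#' period is removed.
#'
#' @param spikes Tibble `unit_id`, `t_s`.
#' @param channel_map Optional tibble `unit_id`, `channel`. When absent the
#'   coincidence rule is skipped with a warning.
#' @param refractory_ms Refractory period in ms (2-3 ms is typical; default
#'   2).
#' @param coincidence_channels Minimum number of distinct channels for the
#'   coincidence rule (default 10).
#' @param coincidence_window_ms Coincidence window in ms (default 0.5).
#' @return List with `spikes` (filtered tibble) and `report` (tibble
#'   `unit_id`, `n_coincident`, `n_refractory`).
#' @export
#' @examples
#' sp <- tibble::tibble(unit_id = "u1", t_s = c(0.1, 0.101, 0.2))
#' qc_spike_trains(sp, refractory_ms = 2)$report
qc_spike_trains <- function(spikes, channel_map = NULL, refractory_ms = 2,
                            coincidence_channels = 10,
                            coincidence_window_ms = 0.5) {
  stopifnot(refractory_ms >= 0)
  spikes <- dplyr::arrange(spikes, .data$unit_id, .data$t_s)
  coincident <- rep(FALSE, nrow(spikes))

  if (is.null(channel_map)) {
    warn("no channel map supplied: coincidence rule skipped")
  } else {
    sp <- dplyr::left_join(spikes, channel_map, by = "unit_id")
    if (any(is.na(sp$channel))) abort("channel map missing some units")
    w <- coincidence_window_ms / 1000
    key <- floor(sp$t_s / w)
    # distinct channels per key; a spike is coincident when its own and the
    # two neighbouring bins together span >= the channel threshold
    per_key <- tapply(sp$channel, key, function(ch) unique(ch))
    nch <- vapply(as.character(key), function(k) {
      ks <- as.character(as.numeric(k) + (-1:1))
      length(unique(unlist(per_key[ks], use.names = FALSE)))
    }, integer(1))
    coincident <- nch >= coincidence_channels
  }

  kept <- spikes[!coincident, ]
  n_coinc <- tapply(coincident, spikes$unit_id, sum)

  refr <- refractory_ms / 1000
  if (nrow(kept) > 0) {
    filt <- kept |>
      dplyr::group_by(.data$unit_id) |>
      dplyr::group_split() |>
      purrr::map(function(tr) {
        t <- tr$t_s
        keep <- rep(TRUE, length(t))
        if (length(t) > 1 && refr > 0) {
          last <- t[1]
          for (i in 2:length(t)) {
            if (t[i] - last < refr) keep[i] <- FALSE else last <- t[i]
          }
        }
        tr$`..keep` <- keep
        tr
      }) |>
      purrr::list_rbind()
    n_refr <- tapply(!filt$`..keep`, filt$unit_id, sum)
    out <- dplyr::select(dplyr::filter(filt, .data$`..keep`), -"..keep")
  } else {
    n_refr <- integer(0)
    out <- kept
  }

  ids <- sort(unique(spikes$unit_id))
  report <- tibble(
    unit_id = ids,
    n_coincident = as.integer(n_coinc[ids] %||% 0),
    n_refractory = as.integer(n_refr[ids] %||% 0)
  )
  report$n_coincident[is.na(report$n_coincident)] <- 0L
  report$n_refractory[is.na(report$n_refractory)] <- 0L
  list(spikes = out, report = report)
}

#' Photo-tagging classification
#'
#' A unit is classified as opsin-tagged when it fires within
#' `latency_max_ms` after at least `reliability_min` of the light pulses
#' (defaults: <= 4 ms and >= 70%). Reliability is the fraction of pulses
#' followed by at least one spike inside the latency window; the median
#' first-spike latency is reported alongside.
#'
#' @param spikes Tibble `unit_id`, `t_s`.
#' @param pulses Tibble with pulse onset times `t_s` (or a numeric vector).
#' @param latency_max_ms Latency window after pulse onset (ms).
#' @param reliability_min Reliability threshold.
#' @param min_pulses Warn when fewer pulses than this are supplied.
#' @return Tibble `unit_id`, `n_pulses`, `reliability`, `median_latency_ms`,
#'   `is_tagged`.
#' @export
#' @examples
#' pulses <- tibble::tibble(t_s = 1:10)
#' sp <- tibble::tibble(unit_id = "u1", t_s = 1:10 + 0.002)
#' tag_units(sp, pulses)
tag_units <- function(spikes, pulses, latency_max_ms = 4,
                      reliability_min = 0.7, min_pulses = 20) {
  pt <- if (is.data.frame(pulses)) pulses$t_s else as.numeric(pulses)
  if (length(pt) == 0) abort("no light pulses supplied")
  if (length(pt) < min_pulses)
    warn(sprintf("only %d pulses: tagging estimates will be noisy",
                 length(pt)))
  wmax <- latency_max_ms / 1000
  spikes |>
    dplyr::group_by(.data$unit_id) |>
    dplyr::group_split() |>
    purrr::map(function(tr) {
      t <- sort(tr$t_s)
      # first spike strictly after each pulse
      idx <- findInterval(pt, t, left.open = FALSE) + 1L
      lat <- ifelse(idx <= length(t), t[idx] - pt, Inf)
      # inclusive upper bound, with a float tolerance so a spike at exactly
      # the latency limit counts
      hit <- lat > 0 & lat <= wmax + 1e-12
      rel <- mean(hit)
      tibble(unit_id = tr$unit_id[1],
             n_pulses = length(pt),
             reliability = rel,
             median_latency_ms = if (any(hit)) 1000 * median(lat[hit])
                                 else NA_real_,
             is_tagged = rel >= reliability_min)
    }) |>
    purrr::list_rbind()
}
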