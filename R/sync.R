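#' Zero-lag spike-count synchrony for a unit pair
#'
#' For each behavioural event, both trains are binned at `bin_s` (10 ms by
#' default) over the event interval and the Pearson correlation of the two
#' count vectors is computed. Events in which either count vector has zero
#' variance are skipped. Correlations are Fisher z-transformed (with |r|
#' capped at 0.9999 so identical trains stay finite), averaged across
#' events, and transformed back: `r_combined = tanh(mean(atanh(r)))`.
#' Symmetric in the two trains.
#'
#' @param train_a,train_b Sorted spike-time vectors (s) or one-unit tibbles
#'   with `t_s`.
#' @param events Tibble `t_start_s`, `t_end_s`; each event must span at
#'   least two bins.
#' @param bin_s Count bin width (s).
#' @return Tibble `n_events_used`, `n_events_skipped`, `mean_z`,
#'   `r_combined` (`NA` with a warning if every event was skipped).
#' @export
#' @examples
#' ev <- tibble::tibble(t_start_s = 0, t_end_s = 1)
#' t1 <- seq(0.005, 0.995, by = 0.05)
#' pair_zero_lag_sync(t1, t1, ev)$r_combined
pair_zero_lag_sync <- function(train_a, train_b, events, bin_s = 0.01) {
  if (is.data.frame(train_a)) train_a <- train_a$t_s
  if (is.data.frame(train_b)) train_b <- train_b$t_s
  train_a <- sort(train_a); train_b <- sort(train_b)
  rs <- purrr::map_dbl(seq_len(nrow(events)), function(i) {
    s <- events$t_start_s[i]; e <- events$t_end_s[i]
    if (e - s < 2 * bin_s) return(NA_real_)
    edges <- seq(s, e, by = bin_s)
    ca <- diff(findInterval(edges, train_a, left.open = TRUE))
    cb <- diff(findInterval(edges, train_b, left.open = TRUE))
    if (sd(ca) == 0 || sd(cb) == 0) return(NA_real_)
    stats::cor(ca, cb)
  })
  used <- !is.na(rs)
  if (!any(used)) {
    warn("synchrony undefined: all events skipped")
    return(tibble(n_events_used = 0L, n_events_skipped = sum(!used),
                  mean_z = NA_real_, r_combined = NA_real_))
  }
  z <- atanh(pmax(pmin(rs[used], 0.9999), -0.9999))
  tibble(n_events_used = sum(used), n_events_skipped = sum(!used),
         mean_z = mean(z), r_combined = tanh(mean(z)))
}

#' Pairwise synchrony across a population
#'
#' Applies [pair_zero_lag_sync()] to every unordered unit pair, optionally
#' annotating each pair by whether it contains a unit of a given class
#' (e.g. an opsin-tagged OT unit).
#'
#' @param spikes Tibble `unit_id`, `t_s`.
#' @param events Tibble `t_start_s`, `t_end_s`.
#' @param units Optional metadata tibble `unit_id`, `class_label`.
#' @param bin_s Count bin width (s).
#' @return Tibble `unit_a`, `unit_b`, synchrony columns, and `pair_class`
#'   when metadata is given.
#' @export
population_sync <- function(spikes, events, units = NULL, bin_s = 0.01) {
  trains <- split_spikes(spikes)
  ids <- names(trains)
  if (length(ids) < 2) abort("need at least two units")
  pairs <- utils::combn(ids, 2)
  out <- purrr::map(seq_len(ncol(pairs)), function(j) {
    a <- pairs[1, j]; b <- pairs[2, j]
    res <- suppressWarnings(
      pair_zero_lag_sync(trains[[a]], trains[[b]], events, bin_s))
    dplyr::mutate(res, unit_a = a, unit_b = b, .before = 1)
  }) |> purrr::list_rbind()
  if (!is.null(units)) {
    cls <- stats::setNames(units$class_label, units$unit_id)
    out$pair_class <- ifelse(cls[out$unit_a] == "OT-PVN" |
                               cls[out$unit_b] == "OT-PVN",
                             "with_OT", "PVN_only")
  }
  out
}

#' Normalized responses to pup-call playback
#'
#' For each played-back call, the firing rate in the 1-s call interval is
#' divided by the rate in the 1 s preceding call onset. Calls with a silent
#' baseline (rate 0) have an undefined ratio and are skipped (counted).
#'
#' @param spike_times Sorted spike times (s) or one-unit tibble with `t_s`.
#' @param call_onsets Call onset times (s); each must have 1 s of
#'   pre-context.
#' @param call_s,baseline_s Interval lengths (s), both default 1.
#' @return List with `responses` (tibble `call`, `rate_call_hz`,
#'   `rate_pre_hz`, `ratio`), `mean_ratio` over defined ratios, and
#'   `n_skipped`.
#' @export
playback_response <- function(spike_times, call_onsets, call_s = 1,
                              baseline_s = 1) {
  if (is.data.frame(spike_times)) spike_times <- spike_times$t_s
  spike_times <- sort(spike_times)
  if (any(call_onsets < baseline_s))
    abort("every call needs 1 s of pre-call context")
  c_call <- count_in_windows(spike_times, call_onsets, call_onsets + call_s)
  c_pre <- count_in_windows(spike_times, call_onsets - baseline_s,
                            call_onsets)
  ratio <- ifelse(c_pre > 0, (c_call / call_s) / (c_pre / baseline_s),
                  NA_real_)
  list(responses = tibble(call = seq_along(call_onsets),
                          rate_call_hz = c_call / call_s,
                          rate_pre_hz = c_pre / baseline_s,
                          ratio = ratio),
       mean_ratio = if (all(is.na(ratio))) NA_real_ else
         mean(ratio, na.rm = TRUE),
       n_skipped = sum(is.na(ratio)))
}
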