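#' Z-scored peri-event time histogram
#'
#' Bins spikes around each event onset (250-ms bins by default; window
#' -20..+40 s, or -10..+20 s for shepherding) and averages counts across
#' events. Each bin's z score is computed against the mean and SD of the
#' event-averaged counts in the pre-event portion of the same histogram.
#' Raw z values are retained; the conventional display clip at +/-3 is
#' applied only when plotting ([autoplot.psth()]).
#'
#' @param spike_times Sorted numeric spike times (s) or one-unit tibble with
#'   `t_s`.
#' @param event_onsets Event onset times (s); at least 2 required.
#' @param window Length-2 peri-event window (s).
#' @param bin_s Bin width (s, default 0.25).
#' @return A `psth` object: tibble `bin_left_s`, `bin_mid_s`, `mean_count`,
#'   `z`, with attributes `bin_s`, `window`, `n_events`,
#'   `baseline_sd_zero` (TRUE when the pre-event SD was 0 and z is
#'   undefined).
#' @export
#' @examples
#' p <- psth_zscore(runif(2000, 0, 100), c(30, 60), window = c(-10, 20))
#' nrow(p) == 30 / 0.25
psth_zscore <- function(spike_times, event_onsets, window = c(-20, 40),
                        bin_s = 0.25) {
  if (is.data.frame(spike_times)) spike_times <- spike_times$t_s
  spike_times <- sort(spike_times)
  if (length(event_onsets) < 2)
    abort("need at least 2 events for a variance estimate")
  edges <- seq(window[1], window[2], by = bin_s)
  n_bins <- length(edges) - 1L
  counts <- vapply(event_onsets, function(t0) {
    diff(findInterval(t0 + edges, spike_times, left.open = TRUE))
  }, numeric(n_bins))
  mean_count <- rowMeans(counts)
  pre <- edges[-1] <= 0  # bins entirely before onset
  mu <- mean(mean_count[pre])
  s <- sd(mean_count[pre])
  z <- if (is.na(s) || s == 0) rep(NA_real_, n_bins) else
    (mean_count - mu) / s
  out <- tibble(bin_left_s = edges[-length(edges)],
                bin_mid_s = edges[-length(edges)] + bin_s / 2,
                mean_count = mean_count, z = z)
  attr(out, "bin_s") <- bin_s
  attr(out, "window") <- window
  attr(out, "n_events") <- length(event_onsets)
  attr(out, "baseline_sd_zero") <- is.na(s) || s == 0
  class(out) <- c("psth", class(out))
  out
}

#' Peri-event window for a behaviour
#'
#' -10..+20 s for shepherding episodes, -20..+40 s otherwise.
#'
#' @param behaviour Behaviour label.
#' @return Length-2 numeric window (s).
#' @export
psth_window_for <- function(behaviour) {
  if (behaviour == "shepherding") c(-10, 20) else c(-20, 40)
}

#' Plot a z-scored PSTH
#'
#' @param object A [psth_zscore()] result.
#' @param clip Display clip for z (default 3, the conventional +/-3 bound);
#'   raw values are not altered.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.psth <- function(object, clip = 3, ...) {
  df <- dplyr::mutate(tibble::as_tibble(object),
                      z_disp = pmax(pmin(.data$z, clip), -clip))
  ggplot2::ggplot(df, ggplot2::aes(.data$bin_mid_s, .data$z_disp)) +
    ggplot2::geom_step() +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "red") +
    ggplot2::labs(x = "time from event onset (s)",
                  y = sprintf("z (clipped at ±%g)", clip)) +
    ggplot2::theme_minimal()
}
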