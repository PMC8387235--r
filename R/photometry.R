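#' Lock-in demodulation of a modulated photometry signal
#'
#' Recovers the fluorescence envelope from a sinusoidally modulated
#' excitation recording by quadrature demodulation: the raw signal is mixed
#' with sine and cosine references at the carrier frequency, both products
#' are low-pass filtered (4th-order Butterworth applied forwards and
#' backwards, i.e. zero-phase, so trial alignment is not biased by filter
#' delay), and the envelope is `2 * sqrt(I^2 + Q^2)`.
#'
#' @param trace A `photometry_trace` with stage `"raw_modulated"`.
#' @param f_ref Carrier (excitation modulation) frequency, Hz; default 400.
#' @param cutoff Low-pass cutoff, Hz; default 20.
#' @return A `photometry_trace` with stage `"demodulated"`.
#' @export
demodulate_lockin <- function(trace, f_ref = 400, cutoff = 20) {
  stopifnot(inherits(trace, "photometry_trace"))
  if (!identical(attr(trace, "stage"), "raw_modulated"))
    abort("trace is not raw_modulated")
  fs <- attr(trace, "fs")
  if (fs <= 2 * f_ref)
    abort("sampling rate must exceed twice the carrier frequency (aliasing)")
  tt <- trace$t_s
  bf <- signal::butter(4, cutoff / (fs / 2), type = "low")
  i_mix <- signal::filtfilt(bf, trace$signal * sin(2 * pi * f_ref * tt))
  q_mix <- signal::filtfilt(bf, trace$signal * cos(2 * pi * f_ref * tt))
  env <- 2 * sqrt(i_mix^2 + q_mix^2)
  photometry_trace(tt, env, fs = fs, stage = "demodulated")
}

#' Trial dF/F
#'
#' For each interval, the baseline fluorescence `F0` is the median of the
#' `baseline_s` window immediately preceding the interval, and the response
#' is the mean over the interval of `(F - F0) / F0`. Scaling the whole
#' trace by any positive constant leaves dF/F unchanged. Intervals whose
#' baseline is non-positive are flagged undefined.
#'
#' @param trace A demodulated `photometry_trace` (or any tibble `t_s`,
#'   `signal`).
#' @param intervals Tibble `t_start_s`, `t_end_s`, within the trace span.
#' @param baseline_s Baseline window length (s), default 1.
#' @return Tibble `trial`, `t_start_s`, `t_end_s`, `f0`, `dff_mean`,
#'   `ok` (FALSE when `F0 <= 0` or windows fall outside the trace).
#' @export
#' @examples
#' tr <- photometry_trace(seq(0, 10, 0.01), rep(2, 1001))
#' dff(tr, tibble::tibble(t_start_s = 5, t_end_s = 6))$dff_mean
dff <- function(trace, intervals, baseline_s = 1) {
  tt <- trace$t_s; ff <- trace$signal
  purrr::map(seq_len(nrow(intervals)), function(i) {
    s <- intervals$t_start_s[i]; e <- intervals$t_end_s[i]
    if (e <= s) abort("interval must have positive length")
    in_base <- tt >= s - baseline_s & tt < s
    in_resp <- tt >= s & tt < e
    if (!any(in_base) || !any(in_resp) || s - baseline_s < min(tt) - 1e-9)
      return(tibble(trial = i, t_start_s = s, t_end_s = e, f0 = NA_real_,
                    dff_mean = NA_real_, ok = FALSE))
    f0 <- median(ff[in_base])
    if (f0 <= 0)
      return(tibble(trial = i, t_start_s = s, t_end_s = e, f0 = f0,
                    dff_mean = NA_real_, ok = FALSE))
    tibble(trial = i, t_start_s = s, t_end_s = e, f0 = f0,
           dff_mean = mean((ff[in_resp] - f0) / f0), ok = TRUE)
  }) |> purrr::list_rbind()
}

#' Per-call dF/F responses and daily summaries
#'
#' Computes [dff()] for every pup-call interval, summarises per day, and
#' optionally re-aligns the daily means to each subject's retrieval-onset
#' day (day 0 = onset) for learning-curve analyses.
#'
#' @param trace A demodulated `photometry_trace`.
#' @param calls Tibble `t_start_s`, `t_end_s`, and optionally `day`.
#' @param onset_day Optional retrieval-onset day for alignment.
#' @param baseline_s Baseline window (s).
#' @return List with `responses` (per call) and `daily` (per-day mean dF/F,
#'   plus `day_rel = day - onset_day` when `onset_day` is given).
#' @export
call_responses <- function(trace, calls, onset_day = NULL, baseline_s = 1) {
  if (nrow(calls) > 1) {
    o <- order(calls$t_start_s)
    if (any(calls$t_start_s[o][-1] < calls$t_end_s[o][-nrow(calls)]))
      abort("calls must not overlap")
  }
  resp <- dff(trace, calls, baseline_s = baseline_s)
  if ("day" %in% names(calls)) resp$day <- calls$day else resp$day <- 1L
  daily <- resp |>
    dplyr::filter(.data$ok) |>
    dplyr::group_by(.data$day) |>
    dplyr::summarise(mean_dff = mean(.data$dff_mean), n_calls = dplyr::n(),
                     .groups = "drop")
  if (!is.null(onset_day)) daily$day_rel <- daily$day - onset_day
  list(responses = resp, daily = daily)
}

#' Joint single-trial spike-photometry correlation
#'
#' Pearson correlation (with its two-sided t-transform p value) between the
#' per-trial population spike modulation (e.g. from
#' [population_trial_modulation()]) and the per-trial cortical calcium
#' response, across observation trials. When an `animal` column is present
#' the pooled correlation and per-animal correlations are both reported.
#'
#' @param trials Tibble with one row per trial.
#' @param mod,dff Column names (tidy evaluation) of the spike modulation and
#'   calcium response.
#' @return List with `pooled` (tibble `r`, `p`, `n`) and `per_animal`
#'   (tibble, `NULL` when no `animal` column).
#' @export
joint_trial_correlation <- function(trials, mod, dff) {
  m <- dplyr::pull(trials, {{ mod }})
  d <- dplyr::pull(trials, {{ dff }})
  if (length(m) < 3) abort("need at least 3 paired trials")
  if (sd(m) == 0 || sd(d) == 0) abort("correlation undefined: zero variance")
  ct <- cor.test(m, d)
  pooled <- tibble(r = unname(ct$estimate), p = ct$p.value, n = length(m))
  per_animal <- NULL
  if ("animal" %in% names(trials)) {
    per_animal <- trials |>
      dplyr::group_by(.data$animal) |>
      dplyr::group_split() |>
      purrr::map(function(g) {
        mm <- dplyr::pull(g, {{ mod }}); dd <- dplyr::pull(g, {{ dff }})
        if (length(mm) < 3 || sd(mm) == 0 || sd(dd) == 0)
          return(tibble(animal = g$animal[1], r = NA_real_, p = NA_real_,
                        n = length(mm)))
        cg <- cor.test(mm, dd)
        tibble(animal = g$animal[1], r = unname(cg$estimate),
               p = cg$p.value, n = length(mm))
      }) |>
      purrr::list_rbind()
  }
  list(pooled = pooled, per_animal = per_animal)
}
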