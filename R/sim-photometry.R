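#' Simulate a fibre-photometry trace
#'
#' The fluorescence envelope is `F0 + sum_i A_i * k(t - t_i) + drift + noise`
#' where `k` is a difference-of-exponentials calcium kernel (rise and decay
#' constants from the config, normalised to unit peak). With
#' `stage = "demodulated"` the envelope itself is returned at
#' `config$photometry_fs_hz`; with `stage = "raw_modulated"` the envelope
#' amplitude-modulates a sinusoidal excitation carrier (default 400 Hz) and
#' must then be recovered with [demodulate_lockin()].
#'
#' @param config A [sim_config()].
#' @param transient_times_s Onset times of calcium transients (s), e.g. pup
#'   call onsets.
#' @param amplitudes Peak transient amplitudes (recycled), same units as the
#'   envelope.
#' @param duration_s Trace length in seconds.
#' @param stage `"demodulated"` (envelope) or `"raw_modulated"` (carrier).
#' @param carrier_hz Excitation carrier frequency for the raw stage.
#' @param raw_fs_hz Sampling rate of the raw stage; must exceed twice the
#'   carrier frequency.
#' @param drift_amp Amplitude of a slow sinusoidal baseline drift.
#' @return List with `trace` (a `photometry_trace`: tibble `t_s`, `signal`
#'   with attributes `fs` and `stage`) and `truth` (tibble `t_s`,
#'   `amplitude`).
#' @export
#' @examples
#' ph <- simulate_photometry(sim_config(seed = 3), transient_times_s = 5,
#'                           amplitudes = 0.3, duration_s = 20)
#' attr(ph$trace, "stage")
simulate_photometry <- function(config, transient_times_s = numeric(0),
                                amplitudes = 0.2, duration_s = 60,
                                stage = c("demodulated", "raw_modulated"),
                                carrier_hz = 400, raw_fs_hz = 5000,
                                drift_amp = 0) {
  cfg <- validate_sim_config(config)
  stage <- match.arg(stage)
  set.seed(cfg$seed + 3000L)
  fs <- if (stage == "raw_modulated") raw_fs_hz else cfg$photometry_fs_hz
  if (fs <= 0) abort("sampling rate must be positive")
  if (stage == "raw_modulated" && fs <= 2 * carrier_hz)
    abort("raw sampling rate must exceed twice the carrier frequency")
  tt <- seq(0, duration_s, by = 1 / fs)
  amplitudes <- rep_len(amplitudes, length(transient_times_s))
  env <- rep(cfg$photometry_f0, length(tt))
  for (i in seq_along(transient_times_s)) {
    env <- env + amplitudes[i] *
      calcium_kernel(tt - transient_times_s[i],
                     cfg$calcium_tau_rise_s, cfg$calcium_tau_decay_s)
  }
  if (drift_amp > 0)
    env <- env + drift_amp * sin(2 * pi * tt / max(duration_s, 1))
  if (cfg$noise_sd > 0)
    env <- env + rnorm(length(tt), 0, cfg$noise_sd)
  signal_out <- if (stage == "raw_modulated")
    env * sin(2 * pi * carrier_hz * tt) else env
  trace <- photometry_trace(tt, signal_out, fs = fs, stage = stage)
  list(trace = trace,
       truth = tibble(t_s = transient_times_s, amplitude = amplitudes))
}

#' Difference-of-exponentials calcium kernel, unit peak
#'
#' `k(t) = (exp(-t/tau_decay) - exp(-t/tau_rise)) / peak` for `t >= 0`, else 0.
#'
#' @param t Times in seconds relative to transient onset.
#' @param tau_rise_s,tau_decay_s Rise and decay constants (s).
#' @return Kernel values, peak 1.
#' @export
calcium_kernel <- function(t, tau_rise_s = 0.2, tau_decay_s = 1.5) {
  stopifnot(tau_decay_s > tau_rise_s, tau_rise_s > 0)
  t_peak <- tau_rise_s * tau_decay_s / (tau_decay_s - tau_rise_s) *
    log(tau_decay_s / tau_rise_s)
  peak <- exp(-t_peak / tau_decay_s) - exp(-t_peak / tau_rise_s)
  out <- ifelse(t >= 0, (exp(-t / tau_decay_s) - exp(-t / tau_rise_s)) / peak,
                0)
  out
}

#' Construct a photometry trace object
#'
#' @param t_s Uniform sample times (s).
#' @param signal Fluorescence values.
#' @param fs Sampling rate (Hz); inferred from `t_s` if missing.
#' @param stage One of `"raw_modulated"`, `"demodulated"`, `"dff"`.
#' @return A tibble of class `photometry_trace` with `fs`/`stage` attributes.
#' @export
photometry_trace <- function(t_s, signal, fs = NULL,
                             stage = c("demodulated", "raw_modulated", "dff")) {
  stage <- match.arg(stage)
  if (is.null(fs)) fs <- 1 / median(diff(t_s))
  out <- tibble(t_s = t_s, signal = signal)
  attr(out, "fs") <- fs
  attr(out, "stage") <- stage
  class(out) <- c("photometry_trace", class(out))
  out
}
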