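#' Configuration for the synthetic cage-session generator
#'
#' Bundles every tunable of the simulator: cage and nest geometry, session
#' length, behavioural event rates, spike-population parameters, photo-tagging
#' parameters, calcium-kernel constants and the retrieval-learning cohorts.
#' Defaults emulate the study system the package targets: an 80 x 40 cm
#' home cage with a nest circle of radius 10 cm, a dam and one co-housed
#' virgin, a paraventricular (PVN) unit population with a minority of
#' event-modulated and opsin-tagged units, and four-day observational
#' retrieval-learning cohorts.
#'
#' @param seed Integer seed; a fixed seed makes every generator
#'   byte-reproducible.
#' @param cage_size Numeric length-2, cage width and height in cm.
#' @param nest_center Numeric length-2, nest centre in cm (origin at the
#'   bottom-left corner of the cage).
#' @param nest_radius_cm Nest radius in cm.
#' @param session_hours Simulated session length in hours.
#' @param traj_fs_hz Trajectory sampling rate in Hz.
#' @param event_rates Named numeric, behavioural event rates in events/hour.
#'   Recognised names: `chase`, `dam_retrieval`, `nest_visit`,
#'   `pup_call_bout`.
#' @param frac_nest_directed Fraction of scripted chases steered so that the
#'   virgin ends nearer the nest than she started (i.e. shepherding).
#' @param chase_duration_s Length-2 range of scripted chase durations (s).
#' @param n_units Number of simulated units.
#' @param frac_modulated Fraction of units modulated by their assigned
#'   behaviour.
#' @param frac_suppressed Among modulated units, fraction suppressed rather
#'   than activated.
#' @param frac_tagged Fraction of units that are opsin-expressing
#'   (photo-taggable).
#' @param baseline_rate_hz Length-2 range; per-unit baseline rates are drawn
#'   log-uniformly from it.
#' @param modulation_gain Multiplicative rate gain inside a modulated unit's
#'   events (activated units use `modulation_gain`, suppressed units its
#'   reciprocal).
#' @param tag_reliability Probability a tagged unit spikes after a light
#'   pulse.
#' @param tag_latency_ms Mean evoked-spike latency in ms (must be <= 4).
#' @param pulse_rate_hz Photo-tagging pulse rate, 2 or 5 Hz.
#' @param n_pulses Number of light pulses in a tagging block.
#' @param calcium_tau_rise_s,calcium_tau_decay_s Difference-of-exponentials
#'   calcium kernel time constants (s); defaults are GCaMP6s-like.
#' @param photometry_fs_hz Sampling rate of the (demodulated) photometry
#'   trace.
#' @param photometry_f0 Baseline fluorescence level (arbitrary units).
#' @param noise_sd Additive Gaussian noise SD on the photometry envelope.
#' @param cohorts Tibble with columns `condition`, `n`, `hazard` giving the
#'   per-day probability that a naive subject acquires retrieval, and
#'   `n_days` observation days. Defaults emulate four-day observation
#'   cohorts in which roughly 73%, 63%, 11% and 30% of subjects acquire
#'   retrieval (no barrier, transparent barrier, opaque barrier,
#'   oxytocin-receptor knockout).
#' @param n_days Number of observation days for the learning cohorts.
#'
#' @return A `sim_config` object (a validated named list).
#' @export
#' @examples
#' cfg <- sim_config(seed = 1, session_hours = 0.5)
#' cfg$nest_radius_cm
sim_config <- function(seed = 1L,
                       cage_size = c(80, 40),
                       nest_center = c(12, 12),
                       nest_radius_cm = 10,
                       session_hours = 2,
                       traj_fs_hz = 5,
                       event_rates = c(chase = 4, dam_retrieval = 0.5,
                                       nest_visit = 4, pup_call_bout = 6),
                       frac_nest_directed = 0.8,
                       chase_duration_s = c(3, 8),
                       n_units = 50,
                       frac_modulated = 0.3,
                       frac_suppressed = 0.25,
                       frac_tagged = 0.04,
                       baseline_rate_hz = c(1, 10),
                       modulation_gain = 3,
                       tag_reliability = 0.9,
                       tag_latency_ms = 2,
                       pulse_rate_hz = 2,
                       n_pulses = 120,
                       calcium_tau_rise_s = 0.2,
                       calcium_tau_decay_s = 1.5,
                       photometry_fs_hz = 100,
                       photometry_f0 = 1,
                       noise_sd = 0.01,
                       cohorts = NULL,
                       n_days = 4) {
  if (is.null(cohorts)) {
    cohorts <- tibble::tibble(
      condition = c("no_barrier", "transparent", "opaque", "oxtr_ko"),
      n = c(15L, 19L, 18L, 10L),
      hazard = c(0.28, 0.22, 0.03, 0.09)
    )
  }
  cfg <- list(
    seed = as.integer(seed),
    cage_size = as.numeric(cage_size),
    nest_center = as.numeric(nest_center),
    nest_radius_cm = nest_radius_cm,
    session_hours = session_hours,
    traj_fs_hz = traj_fs_hz,
    event_rates = event_rates,
    frac_nest_directed = frac_nest_directed,
    chase_duration_s = chase_duration_s,
    n_units = as.integer(n_units),
    frac_modulated = frac_modulated,
    frac_suppressed = frac_suppressed,
    frac_tagged = frac_tagged,
    baseline_rate_hz = baseline_rate_hz,
    modulation_gain = modulation_gain,
    tag_reliability = tag_reliability,
    tag_latency_ms = tag_latency_ms,
    pulse_rate_hz = pulse_rate_hz,
    n_pulses = as.integer(n_pulses),
    calcium_tau_rise_s = calcium_tau_rise_s,
    calcium_tau_decay_s = calcium_tau_decay_s,
    photometry_fs_hz = photometry_fs_hz,
    photometry_f0 = photometry_f0,
    noise_sd = noise_sd,
    cohorts = cohorts,
    n_days = as.integer(n_days)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (length(cfg$cage_size) != 2 || any(cfg$cage_size <= 0))
    abort("cage_size must be two positive lengths (cm)")
  if (cfg$nest_radius_cm <= 0) abort("nest_radius_cm must be > 0")
  nc <- cfg$nest_center
  r <- cfg$nest_radius_cm
  if (nc[1] - r < 0 || nc[2] - r < 0 ||
      nc[1] + r > cfg$cage_size[1] || nc[2] + r > cfg$cage_size[2])
    abort("nest circle must lie inside the cage")
  if (any(cfg$event_rates < 0)) abort("event rates must be >= 0")
  fracs <- c(cfg$frac_modulated, cfg$frac_suppressed, cfg$frac_tagged,
             cfg$frac_nest_directed, cfg$tag_reliability)
  if (any(fracs < 0 | fracs > 1)) abort("fractions must lie in [0, 1]")
  if (cfg$session_hours <= 0) abort("session_hours must be > 0")
  if (any(cfg$baseline_rate_hz <= 0)) abort("baseline rates must be > 0")
  if (cfg$modulation_gain < 0) abort("modulation_gain must be >= 0")
  if (cfg$tag_latency_ms <= 0 || cfg$tag_latency_ms > 4)
    abort("tag_latency_ms must be in (0, 4]")
  if (!cfg$pulse_rate_hz %in% c(2, 5))
    abort("pulse_rate_hz must be 2 or 5 Hz")
  if (any(cfg$cohorts$hazard < 0 | cfg$cohorts$hazard > 1))
    abort("per-day hazards must lie in [0, 1]")
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  cage %g x %g cm, nest (%g, %g) r=%g cm\n",
              x$cage_size[1], x$cage_size[2],
              x$nest_center[1], x$nest_center[2], x$nest_radius_cm))
  cat(sprintf("  session %g h @ %g Hz; units: %d (%.0f%% modulated, %.0f%% tagged)\n",
              x$session_hours, x$traj_fs_hz, x$n_units,
              100 * x$frac_modulated, 100 * x$frac_tagged))
  cat(sprintf("  event rates/h: %s\n",
              paste(names(x$event_rates), x$event_rates, sep = "=",
                    collapse = ", ")))
  invisible(x)
}

#' Nest region helper
#'
#' @param x_cm,y_cm Nest centre coordinates in cm (origin: bottom-left cage
#'   corner).
#' @param radius_cm Nest radius in cm.
#' @return A `nest_region` list with `center` and `radius_cm`.
#' @export
#' @examples
#' nest_region(12, 12, 10)
nest_region <- function(x_cm, y_cm, radius_cm = 10) {
  if (radius_cm <= 0) abort("nest radius must be > 0")
  structure(list(center = c(x_cm, y_cm), radius_cm = radius_cm),
            class = "nest_region")
}

#' @export
print.nest_region <- function(x, ...) {
  cat(sprintf("<nest_region> centre (%g, %g) cm, radius %g cm\n",
              x$center[1], x$center[2], x$radius_cm))
  invisible(x)
}
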