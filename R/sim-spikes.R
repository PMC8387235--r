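#' Simulate an event-modulated spike population
#'
#' Each unit is an inhomogeneous Poisson process with a constant baseline rate
#' drawn log-uniformly from `config$baseline_rate_hz`; inside the events of a
#' unit's assigned behaviour the rate is multiplied by its gain (`g > 1`
#' activated, `g < 1` suppressed, `g = 1` unmodulated). A fraction of units is
#' labelled as opsin-expressing (photo-taggable); those are given the
#' `"OT-PVN"` class label, the rest `"PVN"`.
#'
#' @param config A [sim_config()].
#' @param events Event log tibble (`behaviour`, `t_start_s`, `t_end_s`), e.g.
#'   `simulate_cage_session(config)$events`. Only behaviours among
#'   `behaviours` are used for modulation.
#' @param t_total_s Recording span in seconds (defaults to the configured
#'   session length).
#' @param behaviours Behaviours a modulated unit can be assigned to.
#' @return List with `spikes` (tibble `unit_id`, `t_s`), `units` ground truth
#'   (tibble `unit_id`, `class_label`, `baseline_hz`, `behaviour`,
#'   `direction`, `gain`, `is_tagged`).
#' @export
#' @examples
#' cfg <- sim_config(seed = 2, session_hours = 0.1, n_units = 5)
#' s <- simulate_cage_session(cfg)
#' pop <- simulate_spike_population(cfg, s$events)
#' head(pop$units)
simulate_spike_population <- function(config, events,
                                      t_total_s = NULL,
                                      behaviours = c("shepherding",
                                                     "nest_entry",
                                                     "dam_retrieval")) {
  cfg <- validate_sim_config(config)
  set.seed(cfg$seed + 1000L)
  t_total <- t_total_s %||% (cfg$session_hours * 3600)
  if (nrow(events) > 0 && any(events$t_end_s > t_total + 1e-9))
    abort("events extend beyond the recording span")

  avail <- if ("behaviour" %in% names(events))
    intersect(behaviours, unique(events$behaviour)) else character(0)
  n <- cfg$n_units
  ids <- sprintf("u%03d", seq_len(n))
  baseline <- exp(runif(n, log(cfg$baseline_rate_hz[1]),
                        log(cfg$baseline_rate_hz[2])))
  is_tagged <- runif(n) < cfg$frac_tagged
  modulated <- runif(n) < cfg$frac_modulated & length(avail) > 0
  behaviour <- ifelse(modulated,
                      sample(avail, n, replace = TRUE), NA_character_)
  suppressed <- modulated & runif(n) < cfg$frac_suppressed
  gain <- ifelse(!modulated, 1,
                 ifelse(suppressed, 1 / cfg$modulation_gain,
                        cfg$modulation_gain))
  direction <- ifelse(!modulated, 0L, ifelse(suppressed, -1L, 1L))

  spikes <- purrr::map(seq_len(n), function(i) {
    ev <- if (modulated[i])
      dplyr::filter(events, .data$behaviour == !!behaviour[i]) else
        events[0, ]
    # the recorded animal is the virgin: her nest entries drive modulation
    if (modulated[i] && behaviour[i] == "nest_entry" &&
        "actor" %in% names(ev))
      ev <- dplyr::filter(ev, .data$actor == "virgin")
    t_sp <- sim_inhom_poisson(baseline[i], gain[i],
                              ev$t_start_s, ev$t_end_s, t_total)
    tibble(unit_id = ids[i], t_s = t_sp)
  }) |> purrr::list_rbind()

  units <- tibble(
    unit_id = ids,
    class_label = ifelse(is_tagged, "OT-PVN", "PVN"),
    baseline_hz = baseline,
    behaviour = behaviour,
    direction = direction,
    gain = gain,
    is_tagged = is_tagged
  )
  list(spikes = spikes, units = units)
}

# Piecewise-constant-rate Poisson sampler: rate base_hz outside the (merged)
# event windows and gain * base_hz inside them.
sim_inhom_poisson <- function(base_hz, gain, ev_start, ev_end, t_total) {
  if (base_hz < 0) abort("negative baseline rate")
  iv <- merge_intervals(ev_start, ev_end, t_total)
  # complementary (baseline) segments
  bounds <- sort(unique(c(0, t_total, iv$start, iv$end)))
  seg_start <- bounds[-length(bounds)]
  seg_end <- bounds[-1]
  mid <- (seg_start + seg_end) / 2
  inside <- vapply(mid, function(m)
    any(iv$start <= m & m < iv$end), logical(1))
  rate <- ifelse(inside, gain * base_hz, base_hz)
  out <- vector("list", length(seg_start))
  for (j in seq_along(seg_start)) {
    len <- seg_end[j] - seg_start[j]
    if (len <= 0 || rate[j] <= 0) next
    k <- rpois(1, rate[j] * len)
    if (k > 0) out[[j]] <- sort(runif(k, seg_start[j], seg_end[j]))
  }
  sort(unlist(out) %||% numeric(0))
}

merge_intervals <- function(start, end, t_total) {
  keep <- end > start
  start <- pmax(start[keep], 0); end <- pmin(end[keep], t_total)
  keep2 <- end > start
  start <- start[keep2]; end <- end[keep2]
  if (length(start) == 0)
    return(list(start = numeric(0), end = numeric(0)))
  o <- order(start)
  start <- start[o]; end <- end[o]
  ms <- start[1]; me <- end[1]; rs <- c(); re <- c()
  for (i in seq_along(start)[-1]) {
    if (start[i] <= me) me <- max(me, end[i]) else {
      rs <- c(rs, ms); re <- c(re, me); ms <- start[i]; me <- end[i]
    }
  }
  list(start = c(rs, ms), end = c(re, me))
}

#' Simulate a photo-tagging block
#'
#' Delivers 5-ms blue-light pulses at 2 or 5 Hz. Units flagged as tagged in
#' the ground-truth table emit, after each pulse and with probability
#' `config$tag_reliability`, one evoked spike at a short latency (mean
#' `config$tag_latency_ms`, truncated below 4 ms); all units also fire at
#' their baseline rate throughout the block.
#'
#' @param config A [sim_config()].
#' @param units Ground-truth unit table from [simulate_spike_population()]
#'   (columns `unit_id`, `baseline_hz`, `is_tagged`).
#' @return List with `pulses` (tibble `t_s`, `duration_ms`) and `spikes`
#'   (tibble `unit_id`, `t_s`).
#' @export
simulate_tagging_session <- function(config, units) {
  cfg <- validate_sim_config(config)
  set.seed(cfg$seed + 2000L)
  pulses <- 0.5 + (seq_len(cfg$n_pulses) - 1) / cfg$pulse_rate_hz
  t_end <- max(pulses) + 1
  spikes <- purrr::pmap(
    list(units$unit_id, units$baseline_hz, units$is_tagged),
    function(id, hz, tagged) {
      bg <- sim_inhom_poisson(hz, 1, numeric(0), numeric(0), t_end)
      if (tagged) {
        fire <- runif(length(pulses)) < cfg$tag_reliability
        lat <- pmin(pmax(rnorm(sum(fire), cfg$tag_latency_ms, 0.4),
                         0.2), 3.9) / 1000
        bg <- sort(c(bg, pulses[fire] + lat))
      }
      tibble(unit_id = id, t_s = bg)
    }) |> purrr::list_rbind()
  list(pulses = tibble(t_s = pulses, duration_ms = 5), spikes = spikes)
}
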