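test_that("QC removes refractory violations and multi-channel coincidences", {
  sp <- tibble::tibble(unit_id = "u1", t_s = c(0.100, 0.101, 0.106))
  out <- suppressWarnings(qc_spike_trains(sp, refractory_ms = 2))
  expect_equal(out$spikes$t_s, c(0.100, 0.106))
  expect_equal(out$report$n_refractory, 1L)

  # identical spike on 12 channels: every copy removed
  many <- tibble::tibble(unit_id = sprintf("u%02d", 1:12), t_s = 1)
  cm <- tibble::tibble(unit_id = many$unit_id, channel = 1:12)
  out2 <- qc_spike_trains(many, channel_map = cm)
  expect_equal(nrow(out2$spikes), 0)
  expect_true(all(out2$report$n_coincident == 1))

  # clean Poisson train: refractory removals close to the expected
  # violation rate, no coincidences on distinct channels
  t <- poisson_train(10, 2000, seed = 1)
  sp3 <- tibble::tibble(unit_id = "u1", t_s = t)
  out3 <- suppressWarnings(qc_spike_trains(sp3, refractory_ms = 2))
  expected <- length(t) * 10 * 0.002   # P(next spike < 2 ms) ~ rate * refr
  expect_lt(abs(out3$report$n_refractory - expected), 3 * sqrt(expected) + 3)
  expect_warning(qc_spike_trains(sp3), "coincidence rule skipped")
})

test_that("photo-tagging applies the 70% / 4 ms criteria", {
  pulses <- tibble::tibble(t_s = as.numeric(1:100))
  np <- nrow(pulses)
  perfect <- tibble::tibble(unit_id = "u1", t_s = pulses$t_s + 0.002)
  r <- tag_units(perfect, pulses)
  expect_equal(r$reliability, 1)
  expect_true(r$is_tagged)
  expect_equal(r$median_latency_ms, 2)

  partial <- tibble::tibble(unit_id = "u1",
                            t_s = pulses$t_s[seq_len(round(0.6 * np))] +
                              0.002)
  expect_false(tag_units(partial, pulses)$is_tagged)

  # boundary behaviour: reliability exactly at 0.7 is tagged
  k <- round(0.7 * np)
  edge <- tibble::tibble(unit_id = "u1", t_s = pulses$t_s[1:k] + 0.002)
  expect_true(tag_units(edge, pulses)$is_tagged)
  below <- tibble::tibble(unit_id = "u1", t_s = pulses$t_s[1:(k - 1)] +
                            0.002)
  expect_false(tag_units(below, pulses)$is_tagged)
  # a spike at exactly 4 ms counts; beyond it does not
  at4 <- tibble::tibble(unit_id = "u1", t_s = pulses$t_s + 0.004)
  expect_equal(tag_units(at4, pulses)$reliability, 1)
  past4 <- tibble::tibble(unit_id = "u1", t_s = pulses$t_s + 0.0041)
  expect_equal(tag_units(past4, pulses)$reliability, 0)

  # untagged Poisson unit: reliability ~ 1 - exp(-rate * 4 ms)
  bg <- tibble::tibble(unit_id = "u1", t_s = poisson_train(5, 101, seed = 2))
  rel <- tag_units(bg, pulses)$reliability
  p0 <- 1 - exp(-5 * 0.004)
  expect_lt(abs(rel - p0), 3 * sqrt(p0 * (1 - p0) / np) + 0.01)
  expect_error(tag_units(bg, numeric(0)), "no light pulses")

  # monotone: raising the reliability threshold never tags more units
  for (thr in c(0.5, 0.7, 0.9)) {
    lo <- tag_units(partial, pulses, reliability_min = thr)$is_tagged
    hi <- tag_units(partial, pulses, reliability_min = thr + 0.05)$is_tagged
    expect_true(lo >= hi)
  }
})

test_that("event-aligned rates respect the 40-s nest-entry cap and baselines", {
  ev <- tibble::tibble(t_start_s = 50, t_end_s = 55)
  ar <- event_aligned_rates(seq(50.1, 54.8, length.out = 10), ev,
                            "fixed_10s")
  expect_equal(ar$rate_behaviour_hz, 2)
  expect_equal(ar$rate_baseline_hz, 0)

  long <- tibble::tibble(t_start_s = 100, t_end_s = 200)
  ar2 <- event_aligned_rates(numeric(0), long, "equal_preceding",
                             cap_s = 40)
  expect_equal(ar2$duration_s, 40)
  expect_equal(ar2$rate_behaviour_hz, 0)
  expect_equal(ar2$rate_baseline_hz, 0)

  early <- tibble::tibble(t_start_s = 5, t_end_s = 10)
  expect_false(event_aligned_rates(numeric(0), early, "fixed_10s")$ok)
  expect_identical(baseline_rule_for("nest_entry"),
                   list(baseline_rule = "equal_preceding", cap_s = 40))
  expect_identical(baseline_rule_for("shepherding")$baseline_rule,
                   "fixed_10s")
})

test_that("modulation index follows the signed-contrast formula", {
  expect_equal(modulation_index(10, 5), 100 / 3)
  expect_equal(modulation_index(3, 3), 0)
  expect_equal(modulation_index(2, 0), 100)
  expect_equal(modulation_index(0, 2), -100)
  expect_equal(modulation_index(0, 0), 0)
  set.seed(14)
  a <- rexp(200); b <- rexp(200)
  expect_equal(modulation_index(a, b), -modulation_index(b, a))
  expect_true(all(abs(modulation_index(a, b)) <= 100))
  expect_error(modulation_index(-1, 2), "non-negative")
})

test_that("shift permutation saturates for strong activation and is reproducible", {
  set.seed(3)
  ev <- regular_events(50, 5, 25, t0 = 60)
  t_total <- max(ev$t_end_s) + 100
  base <- poisson_train(3, t_total)
  boost <- unlist(purrr::map2(ev$t_start_s, ev$t_end_s, function(s, e)
    sort(runif(rpois(1, 3 * (e - s) * 3), s, e))))
  train <- sort(c(base, boost))   # gain ~4 inside events
  res <- shuffle_null_test(train, ev, "fixed_10s", t_total,
                           n_shuffles = 1000, seed = 5)
  expect_equal(res$p_act, 1 / 1001)
  expect_true(res$sig950_act)
  res2 <- shuffle_null_test(train, ev, "fixed_10s", t_total,
                            n_shuffles = 1000, seed = 5)
  expect_identical(res$p_act, res2$p_act)
  expect_identical(res$m_shuffles, res2$m_shuffles)
  expect_error(shuffle_null_test(train, ev[0, ], "fixed_10s", t_total),
               "no events")
})

test_that("permutation p values are roughly uniform for null units", {
  ev <- regular_events(30, 5, 20, t0 = 60)
  t_total <- max(ev$t_end_s) + 100
  ps <- vapply(1:60, function(i) {
    tr <- poisson_train(5, t_total, seed = 100 + i)
    shuffle_null_test(tr, ev, "fixed_10s", t_total, n_shuffles = 200,
                      seed = 200 + i)$p_act
  }, numeric(1))
  expect_gt(suppressWarnings(ks.test(ps, "punif"))$p.value, 0.001)
})

test_that("BH flags reproduce the step-up oracle and are monotone in q", {
  mk <- function(p) tibble::tibble(
    p_act = p, p_sup = 1 - p / 2, m_obs = 1,
    family = "all", n_spikes_in_windows = 100)
  none <- fdr_flags(mk(rep(1, 20)))
  expect_true(all(none$direction == "ns"))

  mixed <- fdr_flags(mk(c(rep(0.001, 10), rep(0.9, 90))))
  expect_equal(sum(mixed$direction == "activated"), 10)
  expect_true(all(mixed$direction[1:10] == "activated"))

  # BH oracle: flags match the classical step-up rule on the two-sided p
  p2 <- pmin(1, 2 * pmin(mixed$p_act, mixed$p_sup))
  o <- order(p2)
  thresh <- max(c(0, which(sort(p2) <= 0.05 * seq_along(p2) / length(p2))))
  oracle_flag <- rep(FALSE, length(p2))
  if (thresh > 0) oracle_flag[o[1:thresh]] <- TRUE
  expect_equal(mixed$direction != "ns", oracle_flag)

  for (q in c(0.01, 0.05, 0.1)) {
    n_lo <- sum(fdr_flags(mk(runif(50, 0, 0.2)), q = q)$direction != "ns")
    n_hi <- sum(fdr_flags(mk(runif(50, 0, 0.2)), q = q + 0.05)$direction !=
                  "ns")
    expect_lte(n_lo, n_hi)
  }

  excl <- mk(c(0.001, 0.5))
  excl$n_spikes_in_windows <- c(100, 0)
  fe <- fdr_flags(excl)
  expect_equal(fe$direction[2], "excluded")
  expect_true(is.na(fe$q_value[2]))
})

test_that("PSTH z-scores are near zero under stationarity and positive after a step", {
  set.seed(33)
  onsets <- seq(100, 1900, by = 100)
  flat <- poisson_train(8, 2000)
  p <- psth_zscore(flat, onsets, window = c(-20, 40))
  expect_equal(nrow(p), 60 / 0.25)
  expect_lt(abs(mean(p$z)), 0.75)

  # rate triples for 10 s after each onset
  extra <- unlist(lapply(onsets, function(t0)
    sort(runif(rpois(1, 8 * 10 * 2), t0, t0 + 10))))
  stepped <- sort(c(flat, extra))
  ps <- psth_zscore(stepped, onsets, window = c(-20, 40))
  post <- ps$z[ps$bin_left_s >= 0 & ps$bin_left_s < 10]
  pre <- ps$z[ps$bin_left_s < 0]
  expect_gt(mean(post), 3)
  expect_lt(abs(mean(pre)), 1)
  expect_error(psth_zscore(flat, onsets[1]), "at least 2")
  expect_equal(psth_window_for("shepherding"), c(-10, 20))
  expect_equal(psth_window_for("nest_entry"), c(-20, 40))
})

test_that("pair synchrony behaves at the identical / independent extremes", {
  ev <- tibble::tibble(t_start_s = seq(0, 90, 10), t_end_s = seq(5, 95, 10))
  t1 <- poisson_train(20, 100, seed = 41)
  same <- pair_zero_lag_sync(t1, t1, ev)
  expect_gt(same$r_combined, 0.99)

  t2 <- poisson_train(20, 100, seed = 42)
  indep <- pair_zero_lag_sync(t1, t2, ev)
  expect_lt(abs(indep$r_combined), 0.15)
  swap <- pair_zero_lag_sync(t2, t1, ev)
  expect_equal(indep$r_combined, swap$r_combined)

  # pairs sharing injected common spikes are more synchronous
  common <- poisson_train(10, 100, seed = 43)
  a <- sort(c(poisson_train(10, 100, seed = 44), common))
  b <- sort(c(poisson_train(10, 100, seed = 45), common))
  shared <- pair_zero_lag_sync(a, b, ev)
  expect_gt(shared$r_combined, indep$r_combined)

  expect_warning(silent <- pair_zero_lag_sync(numeric(0), t1, ev),
                 "undefined")
  expect_true(is.na(silent$r_combined))
  expect_equal(silent$n_events_used, 0)
})

test_that("playback responses normalise to the pre-call rate", {
  set.seed(55)
  calls <- seq(10, 1990, by = 10)
  flat <- poisson_train(20, 2000)
  pr <- playback_response(flat, calls)
  # ratio of Poisson counts is slightly upward-biased (~1/E[count])
  expect_lt(abs(pr$mean_ratio - 1), 0.12)

  doubled <- sort(c(flat, unlist(lapply(calls, function(t0)
    sort(runif(rpois(1, 20), t0, t0 + 1))))))
  pr2 <- playback_response(doubled, calls)
  expect_gt(pr2$mean_ratio, 1.7)
  expect_lt(pr2$mean_ratio, 2.4)

  none <- playback_response(numeric(0), calls)
  expect_equal(none$n_skipped, length(calls))
  expect_true(is.na(none$mean_ratio))
  expect_error(playback_response(flat, 0.5), "pre-call")
})

test_that("population trial modulation averages per-unit indices", {
  ev <- regular_events(5, 4, 30, t0 = 50)
  t1 <- poisson_train(10, 300, seed = 61)
  sp1 <- tibble::tibble(unit_id = "u1", t_s = t1)
  single <- population_trial_modulation(sp1, ev)
  ar <- event_aligned_rates(t1, ev, "fixed_10s")
  expect_equal(single$m_mean,
               modulation_index(ar$rate_behaviour_hz, ar$rate_baseline_hz))

  sp2 <- dplyr::bind_rows(sp1, tibble::tibble(
    unit_id = "u2", t_s = poisson_train(5, 300, seed = 62)))
  ab <- population_trial_modulation(sp2, ev)
  ba <- population_trial_modulation(sp2[order(-sp2$t_s), ], ev)
  expect_equal(ab$m_mean, ba$m_mean)
  expect_error(population_trial_modulation(sp1, ev[0, ]), "no trials")

  # a null population fluctuates around zero
  set.seed(63)
  many <- purrr::map(1:30, function(i) tibble::tibble(
    unit_id = sprintf("n%02d", i), t_s = poisson_train(8, 300))) |>
    purrr::list_rbind()
  nullm <- population_trial_modulation(many, ev)
  expect_lt(max(abs(nullm$m_mean)), 25)
})

test_that("modulation_test flags simulated modulated units by direction", {
  cfg <- sim_config(seed = 71, n_units = 24, frac_modulated = 0.5,
                    frac_suppressed = 0.5, modulation_gain = 4,
                    baseline_rate_hz = c(4, 8), session_hours = 1)
  ev <- tibble::tibble(actor = "dam", behaviour = "shepherding",
                       t_start_s = regular_events(50, 6, 40, t0 = 60)$t_start_s,
                       t_end_s = regular_events(50, 6, 40, t0 = 60)$t_end_s,
                       attributes = "")
  t_total <- max(ev$t_end_s) + 100
  pop <- simulate_spike_population(cfg, ev, t_total_s = t_total)
  scan <- modulation_test(pop$spikes, ev, "shepherding", t_total,
                          units = pop$units, n_shuffles = 500, seed = 9)
  res <- dplyr::left_join(scan$results,
                          pop$units[c("unit_id", "direction")],
                          by = "unit_id", suffix = c("", "_true"))
  act <- res[res$direction_true == 1, ]
  sup <- res[res$direction_true == -1, ]
  nul <- res[res$direction_true == 0, ]
  expect_gte(mean(act$direction == "activated"), 0.8)
  expect_gte(mean(sup$direction == "suppressed"), 0.8)
  expect_lte(mean(nul$direction != "ns"), 0.2)
  tidy_like <- scan$results
  expect_true(all(c("p_two", "q_value", "direction") %in% names(tidy_like)))
})
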