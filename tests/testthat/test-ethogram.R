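test_that("distance_to_nest interpolates linearly", {
  nest <- nest_region(0, 0, 10)
  tr <- tibble::tibble(t_s = c(0, 10), x_cm = c(0, 30), y_cm = c(0, 0))
  expect_equal(distance_to_nest(tr, nest, 0), 0)
  expect_equal(distance_to_nest(tr, nest, 10), 30)
  # off-sample query: position at t = 2.5 is (7.5, 0)
  expect_equal(distance_to_nest(tr, nest, 2.5), 7.5)
  tr2 <- tibble::tibble(t_s = c(0, 4), x_cm = c(3, 3), y_cm = c(0, 8))
  expect_equal(distance_to_nest(tr2, nest, 2), sqrt(3^2 + 4^2))
  expect_error(distance_to_nest(tr, nest, 11), "outside")
})

test_that("nest_crossings matches a brute-force inside/outside scan", {
  nest <- nest_region(10, 10, 5)
  # path that never enters
  far <- line_trajectory(c(30, 60), c(30, 30), 20)
  expect_equal(nrow(nest_crossings(far, nest)), 0)
  # straight line through the circle: one entry, one exit
  through <- line_trajectory(c(0, 20), c(10, 10), 20)
  cr <- nest_crossings(through, nest)
  expect_equal(cr$behaviour, c("nest_entry", "nest_exit"))

  # noisy boundary path vs oracle run-length scan
  set.seed(99)
  tt <- seq(0, 100, by = 0.2)
  wob <- tibble::tibble(t_s = tt,
                        x_cm = 10 + cumsum(rnorm(length(tt), 0, 1)),
                        y_cm = 10 + cumsum(rnorm(length(tt), 0, 1)))
  cr2 <- nest_crossings(wob, nest)
  inside <- (wob$x_cm - 10)^2 + (wob$y_cm - 10)^2 <= 25
  oracle <- which(diff(inside) != 0) + 1
  expect_equal(cr2$t_start_s, tt[oracle])
  expect_equal(cr2$behaviour,
               ifelse(inside[oracle], "nest_entry", "nest_exit"))
  # entries and exits strictly alternate
  expect_true(all(rle(cr2$behaviour)$lengths == 1))
})

test_that("chase detection recovers scripted chases and nothing else", {
  traj <- tibble::tibble(t_s = seq(0, 60, 0.2), x_cm = 20, y_cm = 20)
  expect_equal(nrow(detect_chases(traj, traj)), 0)

  s <- simulate_cage_session(sim_config(
    seed = 7, session_hours = 1,
    event_rates = c(chase = 6, dam_retrieval = 0, nest_visit = 1,
                    pup_call_bout = 0)))
  tr <- split(s$trajectories, s$trajectories$animal)
  det <- detect_chases(tr$dam, tr$virgin)
  truth <- s$truth$chases
  expect_gte(interval_sensitivity(truth, det), 0.95)
  # endpoint error at most 1 trajectory sample (0.2 s)
  for (i in seq_len(nrow(truth))) {
    j <- which(det$t_start_s < truth$t_end_s[i] &
                 det$t_end_s > truth$t_start_s[i])
    expect_gte(length(j), 1)
    expect_lte(min(abs(det$t_start_s[j] - truth$t_start_s[i])), 0.2 + 1e-9)
  }
  expect_equal(nrow(detect_chases(tr$dam, tr$virgin, proximity_cm = 0)), 0)
  expect_error(detect_chases(tr$dam, tr$virgin[-1, ]), "time base")
})

test_that("shepherding classification uses only start/end nest distances", {
  nest <- nest_region(0, 0, 10)
  tr <- tibble::tibble(t_s = c(0, 10), x_cm = c(30, 5), y_cm = c(0, 0))
  ch <- tibble::tibble(t_start_s = 0, t_end_s = 10)
  out <- classify_shepherding(ch, tr, nest)
  expect_true(out$is_shepherding)
  expect_equal(out$d_start_cm, 30)
  expect_equal(out$d_end_cm, 5)
  # reversed motion: not shepherding
  tr_rev <- tibble::tibble(t_s = c(0, 10), x_cm = c(5, 30), y_cm = c(0, 0))
  expect_false(classify_shepherding(ch, tr_rev, nest)$is_shepherding)
})

test_that("shepherding classification is invariant to rigid transforms", {
  set.seed(12)
  nest <- nest_region(12, 12, 10)
  tt <- seq(0, 20, 0.2)
  tr <- tibble::tibble(t_s = tt,
                       x_cm = 40 - tt + rnorm(length(tt), 0, 2),
                       y_cm = 12 + rnorm(length(tt), 0, 2))
  ch <- tibble::tibble(t_start_s = c(0, 5), t_end_s = c(4, 18))
  base <- classify_shepherding(ch, tr, nest)
  th <- 0.7; shift <- c(15, -4)
  rot <- function(x, y) list(x = cos(th) * x - sin(th) * y + shift[1],
                             y = sin(th) * x + cos(th) * y + shift[2])
  p <- rot(tr$x_cm, tr$y_cm)
  nc <- rot(nest$center[1], nest$center[2])
  tr2 <- tibble::tibble(t_s = tt, x_cm = p$x, y_cm = p$y)
  nest2 <- nest_region(nc$x, nc$y, nest$radius_cm)
  moved <- classify_shepherding(ch, tr2, nest2)
  expect_equal(moved$is_shepherding, base$is_shepherding)
  expect_equal(moved$d_start_cm, base$d_start_cm, tolerance = 1e-10)
  # uniform time shift
  tr3 <- dplyr::mutate(tr, t_s = t_s + 100)
  ch3 <- dplyr::mutate(ch, t_start_s = t_start_s + 100,
                       t_end_s = t_end_s + 100)
  expect_equal(classify_shepherding(ch3, tr3, nest)$is_shepherding,
               base$is_shepherding)
})

test_that("shepherding rate and the 0.2 events/h reference test behave", {
  expect_equal(shepherding_rate(c(a = 10), 5)$rates$rate_per_h, 2)
  flat <- shepherding_rate(stats::setNames(rep(1, 5), letters[1:5]), 5)
  expect_equal(flat$t, 0)
  set.seed(4)
  rates <- rnorm(14, 1, 0.1)
  counts <- round(rates * 10)
  hot <- shepherding_rate(stats::setNames(counts, paste0("c", 1:14)), 10)
  expect_lt(hot$p_greater, 0.001)
  expect_error(shepherding_rate(c(a = 1), 0), "> 0")
})

test_that("time_in_nest sums dwells and matches a brute-force oracle", {
  expect_equal(time_in_nest(tibble::tibble(behaviour = character(),
                                           t_start_s = double()),
                            3600)$minutes, 0)
  one <- tibble::tibble(behaviour = c("nest_entry", "nest_exit"),
                        t_start_s = c(100, 700))
  expect_equal(time_in_nest(one, 3600)$minutes, 10)
  expect_error(time_in_nest(
    tibble::tibble(behaviour = "nest_exit", t_start_s = 5), 100),
    "malformed")

  set.seed(8)
  bounds <- sort(runif(40, 0, 86400 * 2))
  log <- tibble::tibble(
    behaviour = rep(c("nest_entry", "nest_exit"), 20),
    t_start_s = bounds)
  res <- time_in_nest(log, 86400 * 2)
  oracle_total <- sum(bounds[seq(2, 40, 2)] - bounds[seq(1, 40, 2)])
  expect_equal(sum(res$minutes) * 60, oracle_total)
  # open dwell closed at session end
  open <- tibble::tibble(behaviour = "nest_entry", t_start_s = 3000)
  expect_equal(time_in_nest(open, 3600)$minutes, 10)
})

test_that("retrieval onset applies the 2/10 and 1-success rules", {
  mk <- function(succ_per_day) {
    purrr::map(seq_along(succ_per_day), function(d)
      tibble::tibble(subject = "s", day = d, trial = 1:10,
                     success = seq_len(10) <= succ_per_day[d])) |>
      purrr::list_rbind()
  }
  expect_equal(retrieval_onset(mk(c(0, 1, 3)), "cohoused")$onset_day, 3)
  o <- retrieval_onset(mk(c(0, 0, 0, 0)), "cohoused")
  expect_true(o$censored)
  expect_equal(o$last_day, 4)
  expect_equal(retrieval_onset(mk(c(0, 1, 0, 0)), "observation")$onset_day,
               2)
  # monotone: adding successes can only keep or advance the onset
  base <- mk(c(0, 1, 3, 1))
  for (add_day in 1:4) {
    more <- base
    more$success[more$day == add_day & more$trial == 10] <- TRUE
    expect_lte(retrieval_onset(more, "cohoused")$onset_day,
               retrieval_onset(base, "cohoused")$onset_day)
  }
  gap <- tibble::tibble(subject = "s", day = c(1, 3), trial = 1,
                        success = FALSE)
  expect_error(retrieval_onset(gap, "cohoused"), "without gaps")
})

test_that("day-1 correlations match the direct Pearson formula", {
  d <- tibble::tibble(x = c(1, 4, 7, 9, 12), y = c(0, 2, 3, 5, 9))
  got <- day1_correlation(d, x, y)
  r_hand <- sum((d$x - mean(d$x)) * (d$y - mean(d$y))) /
    sqrt(sum((d$x - mean(d$x))^2) * sum((d$y - mean(d$y))^2))
  t_hand <- r_hand * sqrt(3 / (1 - r_hand^2))
  expect_equal(got$r, r_hand)
  expect_equal(got$p, 2 * pt(abs(t_hand), 3, lower.tail = FALSE))

  exact <- tibble::tibble(x = 1:6, y = 2 * (1:6))
  expect_equal(day1_correlation(exact, x, y)$r, 1)

  set.seed(10)
  big <- tibble::tibble(x = rnorm(1000), y = rnorm(1000))
  expect_lt(abs(day1_correlation(big, x, y)$r), 0.1)
  expect_error(day1_correlation(tibble::tibble(x = rep(1, 5), y = 1:5),
                                x, y), "zero variance")
})

test_that("USV bouts are classed by the 4-8 Hz / 40-90 kHz criteria", {
  mk <- function(rate, freq) tibble::tibble(
    onset_s = seq(0, 1, by = 1 / rate), peak_freq_khz = freq)
  expect_equal(classify_usv_bout(mk(6, 70))$class, "distress")
  expect_equal(classify_usv_bout(mk(2, 70))$class, "other")
  expect_equal(classify_usv_bout(mk(6, 20))$class, "other")
  expect_equal(classify_usv_bout(mk(12, 70))$class, "other")
  expect_error(classify_usv_bout(tibble::tibble(onset_s = 1,
                                                peak_freq_khz = 70)),
               "indeterminate")
})
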