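#' Distance from an animal to the nest centre
#'
#' Linearly interpolates the trajectory at the query times and returns the
#' Euclidean distance (cm) from the animal's centroid to the nest centre.
#'
#' @param trajectory Tibble with `t_s`, `x_cm`, `y_cm` for one animal.
#' @param nest A [nest_region()].
#' @param t Query times in seconds; must lie within the trajectory span.
#' @return Numeric vector of distances (cm).
#' @export
#' @examples
#' tr <- tibble::tibble(t_s = 0:10, x_cm = 0:10 * 3, y_cm = 0)
#' distance_to_nest(tr, nest_region(0, 0, 10), t = 10)
distance_to_nest <- function(trajectory, nest, t) {
  stopifnot(all(c("t_s", "x_cm", "y_cm") %in% names(trajectory)))
  if (any(t < min(trajectory$t_s) - 1e-9 | t > max(trajectory$t_s) + 1e-9))
    abort("query time outside trajectory span")
  x <- approx(trajectory$t_s, trajectory$x_cm, xout = t, rule = 1)$y
  y <- approx(trajectory$t_s, trajectory$y_cm, xout = t, rule = 1)$y
  sqrt((x - nest$center[1])^2 + (y - nest$center[2])^2)
}

#' Nest entry and exit events from a trajectory
#'
#' An entry is scored at the first sample inside the nest circle after the
#' animal was outside; an exit at the first sample outside after being
#' inside, so entries and exits strictly alternate. With centroid-level
#' tracking the head-enters / rear-leaves distinction of pose-based scoring
#' collapses to a single circle-crossing criterion.
#'
#' @param trajectory Tibble with `t_s`, `x_cm`, `y_cm` for one animal;
#'   time stamps must be non-decreasing.
#' @param nest A [nest_region()].
#' @return Tibble of events with `behaviour` in `nest_entry` / `nest_exit`,
#'   `t_start_s == t_end_s` (point events).
#' @export
nest_crossings <- function(trajectory, nest) {
  if (nrow(trajectory) == 0)
    return(tibble(behaviour = character(), t_start_s = double(),
                  t_end_s = double()))
  if (is.unsorted(trajectory$t_s)) abort("trajectory times must be monotone")
  d2 <- (trajectory$x_cm - nest$center[1])^2 +
    (trajectory$y_cm - nest$center[2])^2
  inside <- d2 <= nest$radius_cm^2
  flips <- which(diff(inside) != 0) + 1L
  if (length(flips) == 0)
    return(tibble(behaviour = character(), t_start_s = double(),
                  t_end_s = double()))
  behav <- ifelse(inside[flips], "nest_entry", "nest_exit")
  tibble(behaviour = behav,
         t_start_s = trajectory$t_s[flips],
         t_end_s = trajectory$t_s[flips])
}

#' Detect chase episodes from a pair of trajectories
#'
#' A chase is a maximal run of samples in which (i) the two animals are
#' within `proximity_cm` of each other, (ii) both move at or above
#' `speed_min_cm_s`, and (iii) the dam is behind the virgin's heading (the
#' dam-to-virgin vector has positive dot product with the virgin's
#' velocity). Runs shorter than `min_duration_s` are discarded.
#'
#' @param traj_dam,traj_virgin Tibbles `t_s`, `x_cm`, `y_cm` on a common
#'   clock.
#' @param proximity_cm Maximum inter-animal distance (cm).
#' @param speed_min_cm_s Minimum speed for both animals (cm/s).
#' @param min_duration_s Minimum episode duration (s).
#' @return Tibble `actor = "dam"`, `behaviour = "chase"`, `t_start_s`,
#'   `t_end_s`.
#' @export
detect_chases <- function(traj_dam, traj_virgin, proximity_cm = 8,
                          speed_min_cm_s = 10, min_duration_s = 1) {
  if (nrow(traj_dam) != nrow(traj_virgin) ||
      any(abs(traj_dam$t_s - traj_virgin$t_s) > 1e-9))
    abort("trajectories must share the same time base")
  n <- nrow(traj_dam)
  if (n < 3 || proximity_cm <= 0)
    return(tibble(actor = character(), behaviour = character(),
                  t_start_s = double(), t_end_s = double()))
  dt <- diff(traj_dam$t_s)
  vx_v <- c(NA, diff(traj_virgin$x_cm) / dt)
  vy_v <- c(NA, diff(traj_virgin$y_cm) / dt)
  vx_d <- c(NA, diff(traj_dam$x_cm) / dt)
  vy_d <- c(NA, diff(traj_dam$y_cm) / dt)
  speed_v <- sqrt(vx_v^2 + vy_v^2)
  speed_d <- sqrt(vx_d^2 + vy_d^2)
  dx <- traj_virgin$x_cm - traj_dam$x_cm
  dy <- traj_virgin$y_cm - traj_dam$y_cm
  dist <- sqrt(dx^2 + dy^2)
  behind <- dx * vx_v + dy * vy_v > 0
  ok <- dist <= proximity_cm & speed_v >= speed_min_cm_s &
    speed_d >= speed_min_cm_s & behind
  ok[is.na(ok)] <- FALSE
  r <- rle(ok)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  out <- tibble(actor = "dam", behaviour = "chase",
                t_start_s = traj_dam$t_s[starts[keep]],
                t_end_s = traj_dam$t_s[ends[keep]])
  dplyr::filter(out, .data$t_end_s - .data$t_start_s >= min_duration_s)
}

#' Classify chases as shepherding
#'
#' A chase is a shepherding event when the virgin ends the chase nearer the
#' nest than she started: `d(start) > d(end)`, distances computed with
#' [distance_to_nest()]. The classification is invariant under rigid
#' rotations/translations of all coordinates and under uniform time shifts.
#'
#' @param chases Tibble of chase events (`t_start_s`, `t_end_s`).
#' @param traj_virgin Virgin trajectory tibble.
#' @param nest A [nest_region()].
#' @return The chases tibble with `d_start_cm`, `d_end_cm` and logical
#'   `is_shepherding` added.
#' @export
classify_shepherding <- function(chases, traj_virgin, nest) {
  if (nrow(chases) == 0)
    return(dplyr::mutate(chases, d_start_cm = double(0), d_end_cm = double(0),
                         is_shepherding = logical(0)))
  d0 <- distance_to_nest(traj_virgin, nest, chases$t_start_s)
  d1 <- distance_to_nest(traj_virgin, nest, chases$t_end_s)
  dplyr::mutate(chases, d_start_cm = d0, d_end_cm = d1,
                is_shepherding = d0 > d1)
}

#' Shepherding rate and comparison with a reference rate
#'
#' Computes per-cage shepherding rates (events/hour) and, across cages, a
#' one-sample t test against a reference rate (default 0.2 events/h, the
#' rate of dam-to-virgin chases in the absence of pups). Both the two-sided
#' p value and its halved directional (greater-than) version are reported.
#'
#' @param events Tibble of shepherding events with a `cage` column, or a
#'   numeric vector of per-cage event counts.
#' @param observation_hours Observation time per cage (scalar or per-cage).
#' @param reference Reference rate in events/hour.
#' @return List with `rates` (tibble `cage`, `rate_per_h`) and, when more
#'   than one cage is present, `t`, `df`, `p_two_sided`, `p_greater`.
#' @export
#' @examples
#' shepherding_rate(c(cage1 = 10), observation_hours = 5)$rates
shepherding_rate <- function(events, observation_hours, reference = 0.2) {
  if (any(observation_hours <= 0)) abort("observation_hours must be > 0")
  if (is.numeric(events)) {
    cages <- names(events) %||% as.character(seq_along(events))
    counts <- unname(events)
  } else {
    stopifnot("cage" %in% names(events))
    tb <- dplyr::count(events, .data$cage)
    counts <- tb$n
    cages <- as.character(tb$cage)
  }
  hours <- rep_len(observation_hours, length(counts))
  rates <- tibble(cage = cages, rate_per_h = counts / hours)
  out <- list(rates = rates, reference = reference)
  if (nrow(rates) > 1) {
    if (sd(rates$rate_per_h) == 0) {
      out$t <- 0; out$df <- nrow(rates) - 1
      out$p_two_sided <- 1; out$p_greater <- 0.5
      if (any(rates$rate_per_h != reference)) {
        # all equal but != reference: t undefined (0 SD); report Inf t
        out$t <- Inf * sign(rates$rate_per_h[1] - reference)
        out$p_two_sided <- 0
        out$p_greater <- if (rates$rate_per_h[1] > reference) 0 else 1
      }
    } else {
      tt <- t.test(rates$rate_per_h, mu = reference)
      out$t <- unname(tt$statistic)
      out$df <- unname(tt$parameter)
      out$p_two_sided <- tt$p.value
      # directional report: halve the two-sided p on the observed side
      out$p_greater <- pt(out$t, out$df, lower.tail = FALSE)
    }
  }
  out
}

#' Time in nest per day
#'
#' Sums nest dwell time from alternating entry/exit events. An interval
#' still open at session end is closed at `session_end_s`. Dwells spanning
#' midnight are split across calendar days (day 1 is `[0, 86400)`).
#'
#' @param crossings Tibble with `behaviour` (`nest_entry` / `nest_exit`) and
#'   `t_start_s`, for one animal, time-ordered.
#' @param session_end_s Session end time (s).
#' @return Tibble `day`, `minutes`.
#' @export
time_in_nest <- function(crossings, session_end_s) {
  cr <- dplyr::arrange(crossings, .data$t_start_s)
  cr <- dplyr::filter(cr, .data$behaviour %in% c("nest_entry", "nest_exit"))
  if (nrow(cr) == 0) return(tibble(day = 1L, minutes = 0))
  if (cr$behaviour[1] == "nest_exit")
    abort("malformed log: exit before any entry")
  if (any(diff(match(cr$behaviour, c("nest_entry", "nest_exit"))) == 0))
    abort("malformed log: entries and exits must alternate")
  ent <- cr$t_start_s[cr$behaviour == "nest_entry"]
  ext <- cr$t_start_s[cr$behaviour == "nest_exit"]
  if (length(ext) < length(ent)) ext <- c(ext, session_end_s)
  # split each dwell across day boundaries
  day_len <- 86400
  out <- purrr::map2(ent, ext, function(a, b) {
    days <- seq(floor(a / day_len), floor(max(b - 1e-9, a) / day_len))
    tibble(day = as.integer(days + 1L),
           seconds = pmin(b, (days + 1) * day_len) - pmax(a, days * day_len))
  }) |> purrr::list_rbind()
  out |>
    dplyr::group_by(.data$day) |>
    dplyr::summarise(minutes = sum(.data$seconds) / 60, .groups = "drop")
}

#' Day of retrieval onset
#'
#' Applies the reliable-retrieval criterion per day and returns the first
#' day on which it is met. Under the co-housing rule a subject must succeed
#' in at least two of the ten daily trials; under the observation rule a
#' single success suffices. Subjects that never meet the criterion are
#' censored at their last observed day.
#'
#' @param sessions Tibble `subject`, `day`, `success` (one row per trial).
#' @param rule `"cohoused"` (>= 2/10) or `"observation"` (>= 1 success).
#' @return Tibble `subject`, `onset_day`, `censored`, `last_day`.
#' @export
#' @examples
#' trials <- tidyr::crossing(subject = "v1", day = 1:3, trial = 1:10) |>
#'   dplyr::mutate(success = day == 3 & trial <= 2)
#' retrieval_onset(trials, rule = "cohoused")
retrieval_onset <- function(sessions, rule = c("cohoused", "observation")) {
  rule <- match.arg(rule)
  need <- if (rule == "cohoused") 2L else 1L
  daily <- sessions |>
    dplyr::group_by(.data$subject, .data$day) |>
    dplyr::summarise(n_success = sum(.data$success), .groups = "drop")
  daily |>
    dplyr::group_by(.data$subject) |>
    dplyr::group_split() |>
    purrr::map(function(d) {
      d <- dplyr::arrange(d, .data$day)
      if (!identical(as.integer(d$day), seq(min(d$day), max(d$day))) ||
          min(d$day) != 1L)
        abort(sprintf("subject %s: days must be 1..K without gaps",
                      d$subject[1]))
      hit <- which(d$n_success >= need)
      tibble(subject = d$subject[1],
             onset_day = if (length(hit)) d$day[hit[1]] else NA_integer_,
             censored = length(hit) == 0,
             last_day = max(d$day))
    }) |>
    purrr::list_rbind()
}

#' Day-1 behaviour vs retrieval correlation
#'
#' Pearson correlation (with the t-transform two-sided p value) between a
#' per-cage day-1 behavioural count (e.g. virgin nest entries or shepherding
#' events) and the virgin's day-1 retrieval probability.
#'
#' @param data Tibble holding both variables.
#' @param x,y Column names (tidy evaluation).
#' @return Tibble `r`, `p`, `n`.
#' @export
#' @examples
#' d <- tibble::tibble(entries = c(1, 4, 7, 9, 12),
#'                     retrieval = c(0, .2, .4, .4, .8))
#' day1_correlation(d, entries, retrieval)
day1_correlation <- function(data, x, y) {
  xv <- dplyr::pull(data, {{ x }})
  yv <- dplyr::pull(data, {{ y }})
  if (length(xv) < 3) abort("need at least 3 paired observations")
  if (sd(xv) == 0 || sd(yv) == 0)
    abort("correlation undefined: zero variance")
  ct <- cor.test(xv, yv, method = "pearson")
  tibble(r = unname(ct$estimate), p = ct$p.value, n = length(xv))
}

#' Classify an ultrasonic vocalization bout
#'
#' A bout is a pup distress (isolation) call when its median syllable rate
#' lies in 4-8 Hz and its median peak frequency in 40-90 kHz; otherwise it
#' is classed `"other"`. The syllable rate is the reciprocal of the median
#' inter-onset interval.
#'
#' @param syllables Tibble `onset_s`, `peak_freq_khz`; at least two
#'   syllables are required for a rate estimate.
#' @return Tibble `class` ("distress"/"other"), `bout_rate_hz`,
#'   `median_freq_khz`.
#' @export
#' @examples
#' classify_usv_bout(tibble::tibble(onset_s = seq(0, 1, by = 1/6),
#'                                  peak_freq_khz = 70))
classify_usv_bout <- function(syllables) {
  if (nrow(syllables) < 2)
    abort("indeterminate: need at least two syllables to estimate bout rate")
  rate <- 1 / median(diff(sort(syllables$onset_s)))
  freq <- median(syllables$peak_freq_khz)
  cls <- if (rate >= 4 && rate <= 8 && freq >= 40 && freq <= 90)
    "distress" else "other"
  tibble(class = cls, bout_rate_hz = rate, median_freq_khz = freq)
}
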