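#' Simulate a co-housing cage session
#'
#' Generates centroid trajectories for a dam and a co-housed virgin in a
#' rectangular home cage, together with a scripted behavioural event log:
#' dam-to-virgin chases (a configured fraction steered towards the nest, i.e.
#' shepherding), spontaneous dam pup retrievals (pup drop followed by carry
#' back to the nest), spontaneous nest visits, and pup call bouts. Nest entry
#' and exit events are derived from the generated trajectories themselves, so
#' the event log is consistent with the positional data by construction.
#'
#' Baseline movement is a mean-reverting random walk clipped to the cage;
#' scripted episodes override it. Times are seconds from session start
#' (half-open intervals), positions in cm with the origin at the bottom-left
#' cage corner.
#'
#' @param config A [sim_config()].
#' @return A `cage_session` list:
#'   \describe{
#'     \item{trajectories}{tibble `t_s`, `animal` ("dam"/"virgin"), `x_cm`,
#'       `y_cm`.}
#'     \item{nest}{a [nest_region()].}
#'     \item{events}{tibble `actor`, `behaviour`, `t_start_s`, `t_end_s`,
#'       `attributes` (JSON string).}
#'     \item{truth}{list with `chases` (realized start/end nest distances and
#'       the shepherding label) and `shepherding` (the true shepherding
#'       intervals).}
#'   }
#' @export
#' @examples
#' s <- simulate_cage_session(sim_config(seed = 1, session_hours = 0.2))
#' dplyr::count(s$events, behaviour)
simulate_cage_session <- function(config) {
  cfg <- validate_sim_config(config)
  set.seed(cfg$seed)

  fs <- cfg$traj_fs_hz
  dt <- 1 / fs
  t_total <- cfg$session_hours * 3600
  n <- floor(t_total * fs) + 1L
  tt <- (seq_len(n) - 1L) * dt
  W <- cfg$cage_size[1]; H <- cfg$cage_size[2]
  nest <- nest_region(cfg$nest_center[1], cfg$nest_center[2],
                      cfg$nest_radius_cm)

  # baseline roaming avoids the nest; nest entries come from scripted
  # visits and post-shepherding entries only
  traj_dam <- ou_walk(n, dt, W, H, anchor = c(W * 0.65, H * 0.45),
                      nest = nest)
  traj_vir <- ou_walk(n, dt, W, H, anchor = c(W * 0.75, H * 0.55),
                      nest = nest)

  rate <- function(nm) unname(cfg$event_rates[nm] %||% 0)
  rate_or_0 <- function(nm) { r <- rate(nm); if (is.na(r)) 0 else r }

  events <- list()
  chase_truth <- list()

  # global reservation list: scripted episodes must never overlap each
  # other (an overlapping override would corrupt the earlier script)
  reserved <- matrix(numeric(0), ncol = 2)
  slot_free <- function(a, b)
    nrow(reserved) == 0 || !any(reserved[, 1] < b & reserved[, 2] > a)
  reserve <- function(a, b) reserved <<- rbind(reserved, c(a, b))

  ## ---- chases (dam pursues virgin) -------------------------------------
  n_chase <- rpois(1, rate_or_0("chase") * cfg$session_hours)
  if (n_chase > 0) {
    starts <- sort(runif(n_chase, 30, t_total - 60))
    starts <- starts[vapply(starts, function(t0)
      slot_free(t0 - 5, t0 + max(cfg$chase_duration_s) + 15), logical(1))]
    if (length(starts) > 1) starts <- starts[c(TRUE, diff(starts) > 20)]
    for (t0 in starts) reserve(t0 - 5, t0 + max(cfg$chase_duration_s) + 15)
    nest_directed <- runif(length(starts)) < cfg$frac_nest_directed
    for (i in seq_along(starts)) {
      ep <- script_chase(traj_vir, traj_dam, starts[i], nest_directed[i],
                         cfg, tt, nest)
      traj_vir <- ep$vir; traj_dam <- ep$dam
      d0 <- sqrt(sum((ep$p_start - nest$center)^2))
      d1 <- sqrt(sum((ep$p_end - nest$center)^2))
      chase_truth[[length(chase_truth) + 1L]] <- tibble(
        t_start_s = ep$t0, t_end_s = ep$t1,
        d_start_cm = d0, d_end_cm = d1,
        is_shepherding = d0 > d1, nest_directed = nest_directed[i]
      )
      events[[length(events) + 1L]] <- tibble(
        actor = "dam", behaviour = "chase",
        t_start_s = ep$t0, t_end_s = ep$t1,
        attributes = as.character(jsonlite::toJSON(
          list(nest_directed = nest_directed[i]), auto_unbox = TRUE))
      )
    }
  }
  chases <- if (length(chase_truth)) dplyr::bind_rows(chase_truth) else
    tibble(t_start_s = double(), t_end_s = double(), d_start_cm = double(),
           d_end_cm = double(), is_shepherding = logical(),
           nest_directed = logical())

  # shepherding rows: the chases that truly ended nearer the nest
  shep <- dplyr::filter(chases, .data$is_shepherding)
  if (nrow(shep) > 0) {
    events[[length(events) + 1L]] <- tibble(
      actor = "dam", behaviour = "shepherding",
      t_start_s = shep$t_start_s, t_end_s = shep$t_end_s,
      attributes = ""
    )
  }

  ## ---- spontaneous dam retrievals (pup drop then carry to nest) --------
  n_ret <- rpois(1, rate_or_0("dam_retrieval") * cfg$session_hours)
  if (n_ret > 0) {
    rstarts <- sort(runif(n_ret, 60, t_total - 60))
    rstarts <- rstarts[vapply(rstarts, function(t0)
      slot_free(t0 - 5, t0 + 20), logical(1))]
    if (length(rstarts) > 1)
      rstarts <- rstarts[c(TRUE, diff(rstarts) > 30)]
    for (t0 in rstarts) {
      reserve(t0 - 5, t0 + 20)
      ep <- script_retrieval(traj_dam, t0, cfg, tt, nest)
      traj_dam <- ep$dam
      events[[length(events) + 1L]] <- tibble(
        actor = "dam", behaviour = "pup_drop",
        t_start_s = ep$t_drop, t_end_s = ep$t_drop, attributes = "")
      events[[length(events) + 1L]] <- tibble(
        actor = "dam", behaviour = "dam_retrieval",
        t_start_s = ep$t_carry0, t_end_s = ep$t_carry1, attributes = "")
    }
  }

  ## ---- spontaneous nest visits (both animals) --------------------------
  for (an in c("dam", "virgin")) {
    n_vis <- rpois(1, rate_or_0("nest_visit") * cfg$session_hours)
    if (n_vis == 0) next
    vstarts <- sort(runif(n_vis, 30, t_total - 90))
    vstarts <- vstarts[vapply(vstarts, function(t0)
      slot_free(t0 - 5, t0 + 55), logical(1))]
    if (length(vstarts) > 1)
      vstarts <- vstarts[c(TRUE, diff(vstarts) > 60)]
    for (t0 in vstarts) {
      reserve(t0 - 5, t0 + 55)
      if (an == "dam") traj_dam <- script_nest_visit(traj_dam, t0, cfg, tt, nest)
      else traj_vir <- script_nest_visit(traj_vir, t0, cfg, tt, nest)
    }
  }

  ## ---- pup call bouts (audio-only events) ------------------------------
  n_bout <- rpois(1, rate_or_0("pup_call_bout") * cfg$session_hours)
  if (n_bout > 0) {
    bstarts <- sort(runif(n_bout, 0, t_total - 5))
    dur <- runif(length(bstarts), 1, 3)
    events[[length(events) + 1L]] <- tibble(
      actor = "pup", behaviour = "pup_call_bout",
      t_start_s = bstarts, t_end_s = bstarts + dur,
      attributes = vapply(seq_along(bstarts), function(i)
        as.character(jsonlite::toJSON(list(bout_rate_hz = 6, peak_freq_khz = 65),
                                      auto_unbox = TRUE)), character(1)))
  }

  trajectories <- dplyr::bind_rows(
    tibble(t_s = tt, animal = "dam", x_cm = traj_dam[, 1], y_cm = traj_dam[, 2]),
    tibble(t_s = tt, animal = "virgin", x_cm = traj_vir[, 1], y_cm = traj_vir[, 2])
  )

  ## ---- nest entry/exit derived from the realized trajectories ----------
  crossings <- trajectories |>
    dplyr::group_by(.data$animal) |>
    dplyr::group_split() |>
    purrr::map(function(tr) {
      cr <- nest_crossings(tr, nest)
      if (nrow(cr) > 0) cr$actor <- tr$animal[1]
      cr
    }) |>
    purrr::list_rbind()
  if (nrow(crossings) > 0) {
    # nest_entry rows span the dwell (entry to matching exit, or session
    # end), so event-aligned analyses see the behaviour's duration;
    # nest_exit rows stay point events
    dwells <- crossings |>
      dplyr::group_by(.data$actor) |>
      dplyr::group_split() |>
      purrr::map(function(cr) {
        ent <- cr$t_start_s[cr$behaviour == "nest_entry"]
        ext <- cr$t_start_s[cr$behaviour == "nest_exit"]
        if (length(ent) == 0) return(NULL)
        if (length(ext) < length(ent)) ext <- c(ext, t_total)
        tibble(actor = cr$actor[1], behaviour = "nest_entry",
               t_start_s = ent, t_end_s = ext[seq_along(ent)],
               attributes = "")
      }) |> purrr::list_rbind()
    exits <- dplyr::filter(crossings, .data$behaviour == "nest_exit") |>
      dplyr::transmute(actor = .data$actor, behaviour = .data$behaviour,
                       t_start_s = .data$t_start_s, t_end_s = .data$t_end_s,
                       attributes = "")
    events[[length(events) + 1L]] <- dplyr::bind_rows(dwells, exits)
  }

  events <- dplyr::bind_rows(events)
  if (nrow(events) == 0) {
    events <- tibble(actor = character(), behaviour = character(),
                     t_start_s = double(), t_end_s = double(),
                     attributes = character())
  }
  events <- dplyr::arrange(events, .data$t_start_s, .data$behaviour)

  structure(list(
    trajectories = trajectories,
    nest = nest,
    events = events,
    truth = list(chases = chases, shepherding = shep),
    t_total_s = t_total,
    config = cfg
  ), class = "cage_session")
}

#' @export
print.cage_session <- function(x, ...) {
  cat(sprintf("<cage_session> %.2g h, %d trajectory samples, %d events\n",
              x$t_total_s / 3600, nrow(x$trajectories), nrow(x$events)))
  print(dplyr::count(x$events, .data$behaviour))
  invisible(x)
}

# Mean-reverting (OU) random walk clipped to cage bounds (2-cm wall margin);
# the nest circle, when given, is treated as an obstacle so that baseline
# roaming does not wander into it.
ou_walk <- function(n, dt, W, H, anchor, theta = 0.05, sigma = 6,
                    nest = NULL) {
  x <- matrix(0, n, 2)
  x[1, ] <- anchor + rnorm(2, 0, 4)
  noise <- matrix(rnorm(2 * (n - 1), 0, sigma * sqrt(dt)), n - 1, 2)
  for (i in 2:n) {
    x[i, ] <- x[i - 1, ] + theta * (anchor - x[i - 1, ]) * dt + noise[i - 1, ]
  }
  x[, 1] <- pmin(pmax(x[, 1], 2), W - 2)
  x[, 2] <- pmin(pmax(x[, 2], 2), H - 2)
  if (!is.null(nest)) {
    d <- sqrt((x[, 1] - nest$center[1])^2 + (x[, 2] - nest$center[2])^2)
    rmin <- nest$radius_cm + 1
    inside <- d < rmin
    if (any(inside)) {
      scale <- rmin / pmax(d[inside], 1e-6)
      x[inside, 1] <- nest$center[1] + (x[inside, 1] - nest$center[1]) * scale
      x[inside, 2] <- nest$center[2] + (x[inside, 2] - nest$center[2]) * scale
    }
  }
  x
}

# Overwrite trajectory samples in [t0, t1] with a straight path p0 -> p1.
overwrite_path <- function(traj, tt, t0, t1, p0, p1) {
  idx <- which(tt >= t0 - 1e-9 & tt <= t1 + 1e-9)
  if (length(idx) == 0) return(traj)
  frac <- if (length(idx) == 1) 0 else
    (tt[idx] - tt[idx[1]]) / (tt[idx[length(idx)]] - tt[idx[1]])
  traj[idx, 1] <- p0[1] + frac * (p1[1] - p0[1])
  traj[idx, 2] <- p0[2] + frac * (p1[2] - p0[2])
  traj
}

clip_to_cage <- function(p, cfg, margin = 2) {
  c(min(max(p[1], margin), cfg$cage_size[1] - margin),
    min(max(p[2], margin), cfg$cage_size[2] - margin))
}

# Scripted chase: virgin runs towards (shepherding) or away from the nest at
# ~25 cm/s; the dam tracks 3 cm behind her, so a proximity + speed + relative
# bearing detector can recover the episode.
script_chase <- function(traj_vir, traj_dam, t0, nest_directed, cfg, tt, nest) {
  # snap the episode onto the sample grid so the scripted interval is
  # exactly representable in the trajectory
  t0 <- round(t0 * cfg$traj_fs_hz) / cfg$traj_fs_hz
  i0 <- findInterval(t0, tt)
  p_start <- traj_vir[i0, ]
  d_nest <- sqrt(sum((p_start - nest$center)^2))
  # ensure the virgin starts well outside the nest circle so the flight
  # path is long enough for the speed criterion to hold throughout
  if (d_nest < nest$radius_cm + 20) {
    # relocate the start outside the nest surround, picking the bearing
    # that survives wall clipping with the largest nest distance
    angles <- seq(0, 2 * pi, length.out = 17)[-17]
    cand <- lapply(angles, function(a)
      clip_to_cage(nest$center + (nest$radius_cm + 20) *
                     c(cos(a), sin(a)), cfg))
    dn <- vapply(cand, function(p) sqrt(sum((p - nest$center)^2)),
                 numeric(1))
    p_start <- cand[[which.max(dn)]]
    d_nest <- max(dn)
  }
  speed <- 25
  if (nest_directed) {
    # run towards the nest rim: guaranteed closer at the end
    target <- nest$center + (p_start - nest$center) *
      (nest$radius_cm * 0.5) / d_nest
  } else {
    # flee away from the nest; near walls, pick the bearing that allows the
    # longest run while still ending farther from the nest
    angles <- seq(0, 2 * pi, length.out = 9)[-9]
    cand <- lapply(angles, function(a)
      clip_to_cage(p_start + 30 * c(cos(a), sin(a)), cfg))
    disp <- vapply(cand, function(p) sqrt(sum((p - p_start)^2)), numeric(1))
    dn <- vapply(cand, function(p) sqrt(sum((p - nest$center)^2)),
                 numeric(1))
    away <- dn > d_nest & disp >= 15
    pick <- if (any(away)) which(away)[which.max(disp[away])] else
      which.max(disp)
    target <- cand[[pick]]
  }
  len <- sqrt(sum((target - p_start)^2))
  dur <- max(1.2, min(len / speed, max(cfg$chase_duration_s)))
  dur <- round(dur * cfg$traj_fs_hz) / cfg$traj_fs_hz
  t1 <- min(t0 + dur, tt[length(tt)])
  dirv <- (target - p_start) / max(len, 1e-9)
  dt <- 1 / cfg$traj_fs_hz
  v <- len / (t1 - t0)
  # seed one pre-start sample along the chase direction so the velocity at
  # t0 already reflects the flight, then the chase path itself
  pre_v <- p_start - dirv * v * dt
  pre_d <- pre_v - dirv * 3
  traj_vir <- overwrite_path(traj_vir, tt, t0 - dt, t0, pre_v, p_start)
  traj_dam <- overwrite_path(traj_dam, tt, t0 - dt, t0, pre_d,
                             p_start - dirv * 3)
  traj_vir <- overwrite_path(traj_vir, tt, t0, t1, p_start, target)
  traj_dam <- overwrite_path(traj_dam, tt, t0, t1,
                             p_start - dirv * 3, target - dirv * 3)
  # post-chase holds: the virgin stays where the chase ended (a nest dwell
  # after shepherding), the dam pauses briefly; this keeps the trajectories
  # continuous at the episode boundary
  hold_v <- round(runif(1, 3, 8) * cfg$traj_fs_hz) / cfg$traj_fs_hz
  traj_vir <- overwrite_path(traj_vir, tt, t1, t1 + hold_v, target, target)
  traj_dam <- overwrite_path(traj_dam, tt, t1, t1 + 2,
                             target - dirv * 3, target - dirv * 3)
  list(vir = traj_vir, dam = traj_dam, t0 = t0, t1 = t1,
       p_start = p_start, p_end = target)
}

# Scripted spontaneous retrieval: dam drops a pup away from the nest, pauses,
# then carries it back into the nest and dwells briefly.
script_retrieval <- function(traj_dam, t0, cfg, tt, nest) {
  ang <- runif(1, 0, 2 * pi)
  drop <- clip_to_cage(nest$center +
                         c(cos(ang), sin(ang)) * (nest$radius_cm + 25), cfg)
  t_drop <- t0
  t_carry0 <- t0 + 1
  carry_dur <- runif(1, 3, 6)
  t_carry1 <- t_carry0 + carry_dur
  traj_dam <- overwrite_path(traj_dam, tt, t0, t_carry0, drop, drop)
  traj_dam <- overwrite_path(traj_dam, tt, t_carry0, t_carry1, drop,
                             nest$center)
  t_dwell1 <- t_carry1 + 3
  traj_dam <- overwrite_path(traj_dam, tt, t_carry1, t_dwell1, nest$center,
                             nest$center)
  list(dam = traj_dam, t_drop = t_drop, t_carry0 = t_carry0,
       t_carry1 = t_carry1)
}

# Scripted spontaneous nest visit: walk in, dwell, walk out.
script_nest_visit <- function(traj, t0, cfg, tt, nest) {
  i0 <- findInterval(t0, tt)
  p0 <- traj[i0, ]
  d0 <- sqrt(sum((p0 - nest$center)^2))
  if (d0 < nest$radius_cm + 5) {
    dir_out <- (p0 - nest$center); dir_out <- dir_out /
      max(sqrt(sum(dir_out^2)), 1e-9)
    p0 <- clip_to_cage(nest$center + dir_out * (nest$radius_cm + 10), cfg)
    d0 <- sqrt(sum((p0 - nest$center)^2))
  }
  travel <- d0 / 15
  dwell <- min(rexp(1, 1 / 15), 39)
  t_in1 <- t0 + travel
  t_out0 <- t_in1 + dwell
  ang <- runif(1, 0, 2 * pi)
  p_exit <- clip_to_cage(nest$center +
                           c(cos(ang), sin(ang)) * (nest$radius_cm + 12), cfg)
  t_out1 <- t_out0 + (nest$radius_cm + 12) / 15
  traj <- overwrite_path(traj, tt, t0, t_in1, p0, nest$center)
  traj <- overwrite_path(traj, tt, t_in1, t_out0, nest$center, nest$center)
  traj <- overwrite_path(traj, tt, t_out0, t_out1, nest$center, p_exit)
  traj
}
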