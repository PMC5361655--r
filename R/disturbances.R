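# The five disturbance protocols. Each trial restarts from a stored
# limit-cycle snapshot so conditions never interact; a zero-magnitude
# disturbance of any protocol is bypassed entirely and reproduces the
# undisturbed trajectory bit-exactly.

PROTOCOLS <- c("mmr", "tr", "sr", "trip", "slip")

#' Disturbance specification
#'
#' Constructs one of the five protocols:
#' \describe{
#' \item{mmr}{10 ms square pulses added simultaneously to every muscle's
#'   force, length and velocity afferent, with amplitudes of one maximum
#'   isometric force / one optimum length / one maximum contraction velocity
#'   in the respective normalized units (`amp = 1`).}
#' \item{tr}{Tendon tap: an imposed MTU stretch whose size is the hammer's
#'   kinetic energy divided by the instantaneous muscle tension, capped at
#'   `cap_frac * l_opt` (default hammer: 90 g at 1.5 m/s).}
#' \item{sr}{Imposed ankle dorsiflexion ramp (default 8 degrees at
#'   250 deg/s, i.e. 32 ms) via a stiff external servo torque, held and then
#'   released.}
#' \item{trip}{A free block (default 2.2 kg) standing on the ground in the
#'   swing-foot path; foot-block and block-ground contact use the standard
#'   contact model.}
#' \item{slip}{Stance-side belt/surface speed change of `dv` m/s applied
#'   150 ms after the detected heel strike, completed within `accel_T`.}
#' }
#'
#' @param protocol One of `"mmr"`, `"tr"`, `"sr"`, `"trip"`, `"slip"`.
#' @param t0 Onset time (absolute simulation time, s); for slip the onset is
#'   derived from the heel strike instead, for trip from block placement.
#' @param leg Target leg, `"l"` or `"r"`.
#' @param ... Protocol parameters, see Details above. Common overrides:
#'   `amp` (mmr pulse amplitude; sr ramp amplitude in rad),
#'   `hammer_mass`, `hammer_speed`, `target` ("achilles" or "patellar"),
#'   `vel` (sr ramp speed, rad/s), `dv` (slip belt change, m/s),
#'   `mass`, `x_face` (trip block).
#' @return A `disturbance` list.
#' @export
disturbance <- function(protocol, t0 = 0, leg = "r", ...) {
  protocol <- match.arg(tolower(protocol), PROTOCOLS)
  opts <- list(...)
  base <- list(protocol = protocol, t0 = t0, leg = leg)
  defs <- switch(protocol,
    mmr = list(amp = 1.0, dur = 0.010, bilateral = TRUE),
    tr = list(hammer_mass = 0.090, hammer_speed = 1.5, target = "achilles",
              cap_frac = 0.05, rise = 0.005, hold = 0.005, fall = 0.005),
    sr = list(amp = 8 * pi / 180, vel = 250 * pi / 180, hold = 0.10,
              release = 0.10, kp = 150000, kd = 300, tau_max = 2500),
    trip = list(mass = 2.2, width = 0.10, height = 0.10, x_face = 1e6,
                mu = 0.8, k = 20000, cv = 1.0),
    slip = list(dv = 0.3, after_hs = 0.150, accel_T = 0.050, sign = -1,
                use_snapshot_hs = TRUE))
  unknown <- setdiff(names(opts), names(defs))
  if (length(unknown)) abort(paste0("unknown ", protocol, " options: ",
                                    paste(unknown, collapse = ", ")))
  out <- c(base, modifyList(defs, opts))
  if (protocol == "tr")
    out$ekin <- 0.5 * out$hammer_mass * out$hammer_speed^2
  structure(out, class = "disturbance")
}

# translate to the C++ config block
disturbance_to_cfg <- function(d, ms) {
  if (is.null(d)) return(list(protocol = 0L))
  stopifnot(inherits(d, "disturbance"))
  leg <- if (identical(d$leg, "r")) 1L else 0L
  switch(d$protocol,
    mmr = list(protocol = 1L, leg = leg, t0 = d$t0, amp = d$amp, dur = d$dur,
               bilateral = as.integer(d$bilateral)),
    tr = {
      idx <- switch(d$target,
                    achilles = match(c("SOL", "GAS"), ms$muscle),
                    patellar = match(c("VAS", "RF"), ms$muscle),
                    match(d$target, ms$muscle))
      if (anyNA(idx)) abort("unknown tendon-tap target")
      list(protocol = 2L, leg = leg, t0 = d$t0, muscles = as.integer(idx - 1),
           ekin = d$ekin, cap_frac = d$cap_frac,
           rise = d$rise, hold = d$hold, fall = d$fall)
    },
    sr = list(protocol = 3L, leg = leg, t0 = d$t0, amp = d$amp, vel = d$vel,
              hold = d$hold, release = d$release, kp = d$kp, kd = d$kd,
              tau_max = d$tau_max),
    trip = list(protocol = 4L, leg = leg, t0 = d$t0, mass = d$mass,
                width = d$width, height = d$height, x_face = d$x_face,
                mu = d$mu, k = d$k, cv = d$cv),
    slip = list(protocol = 5L, leg = leg, t0 = d$t0, dv = d$dv,
                after_hs = d$after_hs, accel_T = d$accel_T, sign = d$sign,
                use_snapshot_hs = as.integer(d$use_snapshot_hs)))
}

#' Condition grids of the five experiments
#'
#' MMR and TR probe 16 equal phases over the stride, SR 8 equal phases,
#' TRIP swing fractions within 5-75% of swing, and SLIP belt speed changes
#' of 0.1 to 0.5 m/s in increments of 0.1.
#'
#' @param protocol Protocol name.
#' @param n_trip Number of TRIP swing-fraction conditions (default 8).
#' @return Tibble with `condition` (index) and `value` (stride fraction,
#'   swing fraction, or belt speed change).
#' @export
condition_grid <- function(protocol, n_trip = 8) {
  protocol <- match.arg(tolower(protocol), PROTOCOLS)
  v <- switch(protocol,
    mmr = (seq_len(16) - 0.5) / 16,
    tr = (seq_len(16) - 0.5) / 16,
    sr = (seq_len(8) - 0.5) / 8,
    trip = seq(0.05, 0.75, length.out = n_trip),
    slip = seq(0.1, 0.5, by = 0.1))
  tibble(condition = seq_along(v), value = v)
}

# world position of a foot point along a trajectory (R-side FK on the fly)
.ball_xy <- function(traj, model, leg = "r") {
  fp <- attr(model, "foot_pts")
  i <- function(s) which(model$segment == s)
  l_th <- model$length[i("thigh_l")]; l_sh <- model$length[i("shank_l")]
  o <- if (leg == "l") 0 else 3
  phi_t <- traj$phi_trunk - pi + traj[[c("hip_l", "hip_r")[1 + (leg == "r")]]]
  phi_s <- phi_t - traj[[c("knee_l", "knee_r")[1 + (leg == "r")]]]
  phi_f <- phi_s + pi / 2 + traj[[c("ankle_l", "ankle_r")[1 + (leg == "r")]]]
  kx <- traj$x + l_th * cos(phi_t); ky <- traj$y + l_th * sin(phi_t)
  ax <- kx + l_sh * cos(phi_s); ay <- ky + l_sh * sin(phi_s)
  bx <- ax + cos(phi_f) * fp["ball_x"] - sin(phi_f) * fp["ball_y"]
  by <- ay + sin(phi_f) * fp["ball_x"] + cos(phi_f) * fp["ball_y"]
  tibble(time = traj$time, x = as.numeric(bx), y = as.numeric(by))
}

#' Run one disturbance trial (plus its matched undisturbed trial) from a snapshot
#'
#' @param snap A [steady_snapshot()] result (or its `$snapshot`).
#' @param dist A [disturbance()]; `NULL` for the undisturbed reference.
#' @param params,model,ground As in [simulate_walk()].
#' @param duration Trial length (s) from the snapshot time.
#' @param record_stride Recording stride (default 5 = 0.5 ms at dt 1e-4).
#' @param ... Passed to [simulate_walk()].
#' @return A `gait_sim`.
#' @export
run_trial <- function(snap, dist, params, model = scale_anthropometry(),
                      ground = ground_model(), duration = 1.2,
                      record_stride = 5L, ...) {
  snapshot <- if (!is.null(snap$snapshot)) snap$snapshot else snap
  simulate_walk(params, model = model, ground = ground, duration = duration,
                init = snapshot, disturbance = dist,
                record_stride = record_stride, ...)
}

#' Run a full disturbance protocol across its condition grid
#'
#' Every condition restarts from the same limit-cycle snapshot (single-trial
#' isolation). Stride-phase conditions convert to onset times as
#' `snapshot time + fraction * stride period`; the snapshot is anchored at a
#' heel strike of the target leg, so fraction 0 is heel strike. TRIP
#' conditions place the obstacle so the swing foot's ball reaches its near
#' face at the requested swing fraction, using the undisturbed trial's foot
#' path; geometrically unreachable conditions are flagged unrealizable.
#'
#' @param protocol Protocol name.
#' @param params Reflex parameters (fixture set for the experiment's speed).
#' @param snap A [steady_snapshot()] result.
#' @param model,ground As in [simulate_walk()].
#' @param conditions Condition indices (default: the full grid).
#' @param leg Target leg (must match the snapshot anchor leg).
#' @param duration Trial duration (s); default covers onset + response window.
#' @param overrides Named list of protocol-parameter overrides passed to
#'   [disturbance()].
#' @param ... Passed to [simulate_walk()].
#' @return A `protocol_trials` object: `$trials` (list of `gait_sim`),
#'   `$undisturbed`, `$manifest` tibble, and metadata.
#' @export
run_protocol <- function(protocol, params, snap,
                         model = scale_anthropometry(),
                         ground = ground_model(),
                         conditions = NULL, leg = "r",
                         duration = NULL, overrides = list(), ...) {
  protocol <- match.arg(tolower(protocol), PROTOCOLS)
  grid <- condition_grid(protocol)
  if (!is.null(conditions)) grid <- grid[grid$condition %in% conditions, ]
  snapshot <- snap$snapshot
  stride_T <- snap$stride_period
  t_snap <- snapshot$t
  dur <- if (is.null(duration)) switch(protocol,
    mmr = , tr = , sr = stride_T + 0.35,
    trip = 2.2 * stride_T, slip = stride_T + 0.75) else duration

  undist <- run_trial(snap, NULL, params, model, ground, duration = dur, ...)

  swing_window <- NULL
  if (protocol == "trip") {
    ev <- undist$events
    to <- ev$time[ev$leg == leg & ev$event == "toe_off"]
    hs <- ev$time[ev$leg == leg & ev$event == "heel_strike"]
    if (!length(to)) abort("no toe-off of the target leg in the undisturbed trial")
    # first swing segment of plausible duration (guards residual load blips)
    swing_window <- NULL
    for (t1 in sort(to)) {
      ends <- hs[hs > t1]
      if (length(ends) && (min(ends) - t1) > 0.15 * stride_T) {
        swing_window <- c(t1, min(ends)); break
      }
    }
    if (is.null(swing_window)) abort("no full swing of the target leg in the trial window")
  }

  trials <- vector("list", nrow(grid))
  man <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    val <- grid$value[i]
    unreal <- FALSE
    d <- switch(protocol,
      mmr = rlang::exec(disturbance, "mmr", t0 = t_snap + val * stride_T,
                        leg = leg, !!!overrides),
      tr = rlang::exec(disturbance, "tr", t0 = t_snap + val * stride_T,
                       leg = leg, !!!overrides),
      sr = rlang::exec(disturbance, "sr", t0 = t_snap + val * stride_T,
                       leg = leg, !!!overrides),
      slip = rlang::exec(disturbance, "slip", dv = val, leg = leg, !!!overrides),
      trip = {
        t_hit <- swing_window[1] + val * diff(swing_window)
        ball <- .ball_xy(undist$trajectory, model, leg)
        bx <- approx(ball$time, ball$x, t_hit)$y
        vx <- approx(ball$time, ball$x, t_hit + 0.005)$y - bx
        later <- ball$x[ball$time >= t_hit]
        if (is.na(bx) || vx <= 0 || max(later) < bx + 0.01) unreal <- TRUE
        rlang::exec(disturbance, "trip", t0 = 0, leg = leg,
                    x_face = if (unreal) 1e6 else bx + 0.008, !!!overrides)
      })
    trials[[i]] <- if (unreal) NULL else
      run_trial(snap, d, params, model, ground, duration = dur, ...)
    info <- if (unreal) NULL else trials[[i]]$disturb_info
    man[[i]] <- tibble(
      protocol = protocol, condition = grid$condition[i], value = val,
      onset = if (protocol == "slip") {
        if (unreal || is.null(info)) NA_real_ else info$slip_onset
      } else if (protocol == "trip") {
        if (unreal) NA_real_ else if (info$trip_hit) info$trip_hit_time else NA_real_
      } else d$t0,
      realizable = !unreal &&
        (protocol != "trip" || (!is.null(info) && info$trip_hit == 1)),
      fell = if (is.null(trials[[i]])) NA else trials[[i]]$fall,
      fall_time = if (is.null(trials[[i]]) || !trials[[i]]$fall) NA_real_
                  else trials[[i]]$fall_time)
  }
  structure(list(trials = trials, undisturbed = undist,
                 manifest = dplyr::bind_rows(man),
                 protocol = protocol, leg = leg,
                 stride_period = stride_T, t_snap = t_snap,
                 model = model, params = params),
            class = "protocol_trials")
}

#' @export
print.protocol_trials <- function(x, ...) {
  cat(sprintf("<protocol_trials> %s: %d conditions (%d realizable), stride %.3f s\n",
              toupper(x$protocol), nrow(x$manifest), sum(x$manifest$realizable),
              x$stride_period))
  invisible(x)
}
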