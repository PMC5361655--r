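# Configuration assembly and the main simulation entry point. The fixed-step
# core (C++) advances rigid-body dynamics, muscle states, delayed reflex
# control and ground contact together; everything here is marshalling,
# naming and tidy output.

#' Ground / treadmill model
#'
#' Compliant ground contact: linear normal spring with penetration-rate
#' damping, and anchor-based (stick-slip) Coulomb friction whose anchors
#' convect with the belt, so a moving belt drags a sticking foot. Belt
#' velocities are per side (split-belt); zero means overground.
#'
#' @param belt_left,belt_right Belt surface velocity (m/s, +x forward).
#' @param k_normal Normal stiffness (N/m per contact point).
#' @param v_ref Penetration-rate damping reference velocity (m/s).
#' @param k_tangent,c_tangent Tangential anchor stiffness (N/m) and damping (N s/m).
#' @param mu_stick,mu_slide Static and kinetic friction coefficients.
#' @return A `ground_model` list.
#' @export
ground_model <- function(belt_left = 0, belt_right = 0,
                         k_normal = 80000, v_ref = 0.03,
                         k_tangent = 8000, c_tangent = 300,
                         mu_stick = 0.9, mu_slide = 0.8) {
  structure(list(kn = k_normal, vref = v_ref, kt = k_tangent, ct = c_tangent,
                 mu_s = mu_stick, mu_k = mu_slide,
                 belt = c(belt_left, belt_right)),
            class = "ground_model")
}

#' Default reflex-control parameters
#'
#' Named vector of the phase-gated reflex network's gains, offsets and
#' thresholds (dimensionless or in normalized afferent units). These are
#' starting values; optimized sets for the shipped walking speeds live in
#' `inst/extdata/` and are loaded with [read_reflex_params()].
#'
#' @return Named numeric vector.
#' @export
default_reflex_params <- function() {
  c(G_SOL = 1.2, G_TA = 1.1, loff_TA = 0.72, G_SOLTA = 0.6, G_GAS = 1.1,
    G_VAS = 1.2, q_ko = 0.15, k_ko = 2.0, k_dsVAS = 0.6,
    th_ref = 0.10, k_p = 1.5, k_d = 0.3,
    c_GLU_bal = 0.7, c_HFL_bal = 0.7, c_HAM_bal = 0.5,
    ds_HFL = 0.4, ds_GLU = 0.25, sw_BFSH = 0.2, frac_BFSH = 0.3,
    G_HFL = 0.35, loff_HFL = 0.65, G_HAMHFL = 0.5, loff_HAM = 0.85,
    G_HAM = 0.25, G_GLU_sw = 0.25, k_lean_HFL = 0.35,
    s0_VAS = 0.09, s0_SOL = 0.02, s0_GAS = 0.02, s0_HAM = 0.05,
    s0_GLU = 0.05, s0_HFL = 0.05, s0_RF = 0.01, s0_BFSH = 0.01, s0_TA = 0.01)
}

#' Read / write reflex parameters as a flat name-value text table
#'
#' One `name value` pair per line, so optimized parameter sets are diffable.
#'
#' @param path File path.
#' @return For `read_reflex_params`, a named numeric vector.
#' @export
read_reflex_params <- function(path) {
  df <- utils::read.table(path, header = FALSE, col.names = c("name", "value"),
                          stringsAsFactors = FALSE)
  setNames(df$value, df$name)
}

#' @rdname read_reflex_params
#' @param params Named numeric vector.
#' @export
write_reflex_params <- function(params, path) {
  stopifnot(is.numeric(params), !is.null(names(params)))
  writeLines(sprintf("%s %.12g", names(params), params), path)
  invisible(path)
}

#' Shipped optimized parameter set for one experiment speed
#'
#' @param speed One of 0.83, 0.97, 1.11, 1.20 (m/s), the walking speeds of
#'   the five disturbance experiments.
#' @param subject `"default"` for the 1.8 m / 80 kg (75 kg at 1.20 m/s) body;
#'   `"mmr"` for the 1.75 m / 64 kg body of the afferent-stimulation study.
#' @return Named numeric parameter vector.
#' @export
walking_params <- function(speed, subject = "default") {
  tag <- sprintf("%03.0f", round(speed * 100))
  fn <- if (identical(subject, "mmr")) "reflex_params_mmr_097.txt"
        else paste0("reflex_params_", tag, ".txt")
  path <- system.file("extdata", fn, package = "reflexgait")
  if (!nzchar(path)) abort(paste0("no shipped parameter set for speed ", speed))
  read_reflex_params(path)
}

#' Body model matched to one experiment's subjects
#'
#' The afferent-stimulation experiment reports 1.75 m / 64 kg subjects; the
#' surface-slip experiment's BMI of 23 gives 75 kg at the default 1.8 m
#' stature; the remaining experiments use the default 1.8 m / 80 kg body.
#'
#' @param experiment One of "MMR", "TR", "SR", "TRIP", "SLIP".
#' @return A [scale_anthropometry()] body model.
#' @export
experiment_body <- function(experiment) {
  switch(toupper(experiment),
    MMR = scale_anthropometry(1.75, 64),
    SLIP = scale_anthropometry(1.8, 75),
    scale_anthropometry(1.8, 80))
}

#' Walking speed of each experiment (m/s)
#' @param experiment One of "MMR", "TR", "SR", "TRIP", "SLIP".
#' @return Target speed in m/s.
#' @export
experiment_speed <- function(experiment) {
  switch(toupper(experiment),
    MMR = 0.97, TR = 0.83, SR = 0.97, TRIP = 1.11, SLIP = 1.20,
    abort("unknown experiment"))
}

.Q_NAMES <- c("x", "y", "phi_trunk",
              "hip_l", "knee_l", "ankle_l", "hip_r", "knee_r", "ankle_r")

traj_colnames <- function() {
  musvars <- c("act", "stim", "l_ce", "v_ce", "force", "l_mtu")
  muscols <- unlist(lapply(c("l", "r"), function(leg)
    unlist(lapply(tolower(MUSCLES), function(m)
      paste(m, leg, musvars, sep = "_")))))
  c("time", .Q_NAMES, paste0("d", .Q_NAMES),
    "grf_x_l", "grf_y_l", "grf_x_r", "grf_y_r",
    "load_l", "load_r", "wst_l", "wst_r",
    "stride_frac_l", "stride_frac_r", "phase_l", "phase_r",
    "belt_l", "belt_r", "ke", "pe", "e_met", muscols)
}

#' Forward kinematics of the walker's key points
#'
#' Pure-R mirror of the segment geometry, used for plotting and for
#' independent energy checks in the tests.
#'
#' @param model Body model.
#' @param q Generalized coordinates (length 9).
#' @return Tibble of named points (hip, knees, ankles, heel/ball, head, coms)
#'   with world coordinates.
#' @export
segment_positions <- function(model, q) {
  stopifnot(length(q) == 9)
  dir <- function(a) c(cos(a), sin(a))
  i <- function(s) which(model$segment == s)
  l_th <- model$length[i("thigh_l")]; l_sh <- model$length[i("shank_l")]
  fp <- attr(model, "foot_pts")
  hip <- c(q[1], q[2]); phit <- q[3]
  rows <- list(
    tibble(point = "hip", leg = "c", x = hip[1], y = hip[2]),
    tibble(point = "head", leg = "c",
           x = hip[1] + model$length[i("hat")] * cos(phit),
           y = hip[2] + model$length[i("hat")] * sin(phit)),
    tibble(point = "com_hat", leg = "c",
           x = hip[1] + model$com_offset[i("hat")] * cos(phit),
           y = hip[2] + model$com_offset[i("hat")] * sin(phit)))
  for (leg in c("l", "r")) {
    o <- if (leg == "l") 4 else 7
    phi_t <- phit - pi + q[o]
    knee <- hip + l_th * dir(phi_t)
    phi_s <- phi_t - q[o + 1]
    ankle <- knee + l_sh * dir(phi_s)
    phi_f <- phi_s + pi / 2 + q[o + 2]
    R <- matrix(c(cos(phi_f), sin(phi_f), -sin(phi_f), cos(phi_f)), 2)
    heel <- ankle + as.numeric(R %*% fp[c("heel_x", "heel_y")])
    ball <- ankle + as.numeric(R %*% fp[c("ball_x", "ball_y")])
    com_th <- hip + model$com_offset[i("thigh_l")] * dir(phi_t)
    com_sh <- knee + model$com_offset[i("shank_l")] * dir(phi_s)
    com_ft <- ankle + as.numeric(R %*% c(0.10 * model$length[i("foot_l")],
                                         -0.5 * attr(model, "ankle_height")))
    rows <- c(rows, list(
      tibble(point = c("knee", "ankle", "heel", "ball",
                       "com_thigh", "com_shank", "com_foot"),
             leg = leg,
             x = c(knee[1], ankle[1], heel[1], ball[1], com_th[1], com_sh[1], com_ft[1]),
             y = c(knee[2], ankle[2], heel[2], ball[2], com_th[2], com_sh[2], com_ft[2]))))
  }
  dplyr::bind_rows(rows)
}

# standing-start pose: front (left) leg extended ahead, rear leg pushing
initial_pose <- function(model, v0 = 1.0, lean = 0.07) {
  q <- c(0, 0, pi / 2 - lean, 0.32, 0.06, -0.02, -0.10, 0.22, -0.08)
  pts <- segment_positions(model, q)
  low <- min(pts$y[pts$point %in% c("heel", "ball")])
  q[2] <- -low - 0.0005   # lowest contact point just touching the ground
  qd <- c(v0, 0, 0, 0, 0, 0, 0, 0, 0)
  list(q = q, qd = qd)
}

build_cfg <- function(params, model, ground, duration, dt, record_stride,
                      init, disturbance, snapshot_at, gravity, contact,
                      muscles_on, pin_base, control_mode, stimulations,
                      fall_frac, metabolic, a0) {
  ms <- muscle_set(model)
  jl <- attr(model, "joint_limits")
  dist_cfg <- disturbance_to_cfg(disturbance, ms)
  list(
    dt = dt, duration = duration, record_stride = as.integer(record_stride),
    gravity = gravity, pin_base = as.integer(pin_base),
    contact_on = as.integer(contact), muscles_on = as.integer(muscles_on),
    fall_frac = fall_frac,
    body = body_to_cfg(model),
    muscles = muscles_to_cfg(ms),
    control = params,
    ground = unclass(ground),
    disturb = dist_cfg,
    jlim_lo = jl[, 1], jlim_hi = jl[, 2], jlim_k = 1000, jlim_d = 50,
    debounce = 0.020,
    foot_pts = unname(attr(model, "foot_pts")),
    delay_trunk = 0.005, delay_load = 0.010, delay_knee = 0.010,
    metabolic = metabolic,
    control_mode = if (identical(control_mode, "external")) 1L else 0L,
    stim_ext = if (is.null(stimulations)) rep(0.01, 18) else stimulations,
    init = init,
    snapshot_at = snapshot_at
  )
}

#' Simulate walking (or any motion) of the reflex-controlled walker
#'
#' Advances the full neuromechanical model with a fixed-step semi-implicit
#' Euler integrator. Deterministic: identical configurations give
#' bit-identical trajectories.
#'
#' @param params Named reflex-parameter vector (see [default_reflex_params()]).
#' @param model Body model from [scale_anthropometry()].
#' @param duration Simulated time (s).
#' @param dt Integrator step (s); keep within 1e-4 to 5e-4.
#' @param ground [ground_model()].
#' @param v0 Initial forward velocity (m/s) for the standing start.
#' @param init `"stand"`, a `list(q, qd)` pose, or a snapshot from a previous
#'   run (`sim$final` or `sim$snapshot`) to continue bit-exactly.
#' @param disturbance Optional [disturbance()] specification.
#' @param record_stride Record every n-th step (10 = 1 kHz at dt 1e-4).
#' @param snapshot_at Optional `list(leg = "l"/"r", after = seconds)`: capture a
#'   full restartable state snapshot at the first heel strike of that leg
#'   after the given time.
#' @param gravity Gravitational acceleration (m/s^2).
#' @param contact,muscles Logical switches (for ballistic / passive tests).
#' @param pin_base Pin the hip translation (for pendulum-style tests).
#' @param control `"reflex"` (default) or `"external"` (fixed stimulations).
#' @param stimulations Length-18 stimulation vector when `control = "external"`.
#' @param fall_frac Fall threshold: fraction of standing hip height.
#' @param metabolic Energy-rate constants `c(activation, shortening, lengthening)`.
#' @param a0 Initial muscle activations.
#' @return A `gait_sim` object: `$trajectory` tibble, `$events`, fall and
#'   distance summaries, a captured `$snapshot` (if requested), the `$final`
#'   state, and `$disturb_info`.
#' @export
simulate_walk <- function(params = default_reflex_params(),
                          model = scale_anthropometry(),
                          duration = 10, dt = 1e-4,
                          ground = ground_model(),
                          v0 = 1.0, init = "stand",
                          disturbance = NULL,
                          record_stride = 10L,
                          snapshot_at = NULL,
                          gravity = 9.81,
                          contact = TRUE, muscles = TRUE, pin_base = FALSE,
                          control = "reflex", stimulations = NULL,
                          fall_frac = 0.7,
                          metabolic = c(0.5, 0.25, 0.05),
                          a0 = 0.01) {
  init_cfg <- if (identical(init, "stand")) {
    c(initial_pose(model, v0), list(type = "pose", a0 = a0))
  } else if (!is.null(init$q) && is.null(init$buffers)) {
    c(init, list(type = "pose", a0 = a0))
  } else {
    if (!is.null(init$buffers) && abs(init$dt - dt) > 1e-12)
      abort("snapshot dt does not match simulation dt")
    list(type = "snapshot", snapshot = init)
  }
  snap_cfg <- if (is.null(snapshot_at)) NULL else
    list(leg = if (identical(snapshot_at$leg, "r")) 1L else 0L,
         after = snapshot_at$after)
  cfg <- build_cfg(params, model, ground, duration, dt, record_stride,
                   init_cfg, disturbance, snap_cfg, gravity, contact,
                   muscles, pin_base, control, stimulations, fall_frac,
                   metabolic, a0)
  res <- rg_sim_cpp(cfg)
  traj <- as_tibble(as.data.frame(res$traj))
  names(traj) <- traj_colnames()
  events <- tibble(time = as.numeric(res$events_t),
                   leg = ifelse(res$events_leg == 0, "l", "r"),
                   event = ifelse(res$events_type == 0, "heel_strike", "toe_off"))
  structure(list(
    trajectory = traj,
    events = events,
    fall = as.logical(res$fall),
    fall_time = res$fall_time,
    distance = res$distance,
    duration_done = res$duration_done,
    t_start = res$t_start,
    energy = res$energy,
    stride_period = res$stride_T,
    snapshot = res$snapshot,
    final = res$final,
    disturb_info = res$disturb_info,
    disturbance = disturbance,
    params = params, model = model, dt = dt,
    ground = ground
  ), class = "gait_sim")
}

#' @export
print.gait_sim <- function(x, ...) {
  cat(sprintf(
    "<gait_sim> %.2f s simulated, %.2f m walked (%.3f m/s)%s, %d events\n",
    x$duration_done, x$distance,
    ifelse(x$duration_done > 0, x$distance / x$duration_done, NA),
    if (x$fall) sprintf(", FELL at %.2f s", x$fall_time) else "",
    nrow(x$events)))
  invisible(x)
}

#' Advance the model by one (or a few) integrator steps
#'
#' Thin wrapper over the fixed-step core for stepping a known state with
#' explicit stimulations; used to probe the plant without the reflex layer.
#'
#' @param state A pose `list(q, qd)` or snapshot.
#' @param stimulations Length-18 per-muscle stimulation vector in `[0, 1]`.
#' @param n_steps Number of steps.
#' @inheritParams simulate_walk
#' @return A `gait_sim` object covering the stepped interval.
#' @export
step_dynamics <- function(state, stimulations, model = scale_anthropometry(),
                          n_steps = 1L, dt = 1e-4, ground = ground_model(),
                          gravity = 9.81, contact = TRUE, muscles = TRUE,
                          pin_base = FALSE, ...) {
  simulate_walk(params = default_reflex_params(), model = model,
                duration = n_steps * dt, dt = dt, ground = ground,
                init = state, control = "external",
                stimulations = stimulations, record_stride = 1L,
                gravity = gravity, contact = contact, muscles = muscles,
                pin_base = pin_base, ...)
}

# steady-gait snapshot: walk to steady state, capture full state at a heel strike
#' Capture a steady-gait (limit-cycle) snapshot
#'
#' Runs the model from a standing start until gait has settled, then captures
#' the complete restartable state at the first heel strike of `leg` after
#' `settle` seconds. Disturbance trials all launch from such snapshots so
#' conditions never interact.
#'
#' @inheritParams simulate_walk
#' @param leg Which leg's heel strike anchors the snapshot ("r" default).
#' @param settle Settling time before the capture (s).
#' @return List with `snapshot` (restartable state), `stride_period` (s) and
#'   the settling `sim`.
#' @export
steady_snapshot <- function(params, model = scale_anthropometry(),
                            v0 = 1.0, leg = "r", settle = 6,
                            dt = 1e-4, ground = ground_model(), ...) {
  sim <- simulate_walk(params, model = model, duration = settle + 2.5,
                       dt = dt, ground = ground, v0 = v0,
                       snapshot_at = list(leg = leg, after = settle),
                       record_stride = 50L, ...)
  if (sim$fall) abort(sprintf("model fell at %.2f s; cannot take steady snapshot",
                              sim$fall_time))
  if (is.null(sim$snapshot)) abort("no heel strike found after the settling time")
  list(snapshot = sim$snapshot, stride_period = sim$stride_period, sim = sim)
}
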