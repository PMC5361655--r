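# steady walking on the shipped parameter fixtures, snapshot/trial plumbing,
# and the per-protocol trial behaviors that need a walking gait

test_that("shipped parameter sets walk 30 s at every experiment speed", {
  cases <- list(c(0.83, 80), c(0.97, 80), c(1.11, 80), c(1.20, 75))
  for (cs in cases) {
    v <- cs[1]
    model <- scale_anthropometry(1.8, cs[2])
    p <- walking_params(v)
    sim <- simulate_walk(p, model = model, duration = 36, v0 = v,
                         record_stride = 100L)
    expect_false(sim$fall)
    expect_gte(sim$duration_done, 30)
    tr <- sim$trajectory
    win <- tr$time >= 3
    v_avg <- (tail(tr$x[win], 1) - tr$x[win][1]) /
      (tail(tr$time[win], 1) - tr$time[win][1])
    expect_lt(abs(v_avg - v), 0.05)
  }
})

test_that("online event detection agrees with offline re-derivation", {
  sn <- fixture_snapshot(0.97)
  sim <- sn$sim
  # use the smoothed stance weight as the contact indicator: the raw normal
  # force rings at the contact-spring frequency
  hist <- tibble::tibble(time = sim$trajectory$time,
                         contact_l = sim$trajectory$wst_l > 0.5,
                         contact_r = sim$trajectory$wst_r > 0.5)
  off <- detect_gait_events(hist)
  on_hs <- sim$events$time[sim$events$event == "heel_strike" &
                             sim$events$leg == "r"]
  off_hs <- off$events$time[off$events$event == "heel_strike" &
                              off$events$leg == "r"]
  on_hs <- on_hs[on_hs > min(off_hs) - 0.1]
  # same number of (debounced) strides, times within the coarse sampling + debounce
  expect_equal(length(on_hs), sum(off_hs > min(off_hs) - 0.1))
  # online events are backdated through the debounce; the smoothed stance
  # weight crosses 0.5 about one debounce + fade later
  expect_lt(max(abs(on_hs - off_hs[seq_along(on_hs)])), 0.05)
})

test_that("zero-magnitude disturbances reproduce the undisturbed run bit-exactly", {
  sn <- fixture_snapshot(0.97)
  p <- fixture_params(0.97); m <- sn$model
  und <- run_trial(sn, NULL, p, m, duration = 0.8)
  t0 <- sn$snapshot$t + 0.3 * sn$stride_period
  nulls <- list(disturbance("mmr", t0 = t0, amp = 0),
                disturbance("tr", t0 = t0, hammer_speed = 0),
                disturbance("sr", t0 = t0, amp = 0),
                disturbance("trip", mass = 0),
                disturbance("slip", dv = 0))
  for (d in nulls) {
    tr <- run_trial(sn, d, p, m, duration = 0.8)
    expect_identical(tr$trajectory, und$trajectory)
  }
})

test_that("afferent pulses evoke extensor spikes after the transport delay", {
  sn <- fixture_snapshot(0.97)
  p <- fixture_params(0.97); m <- sn$model
  t0 <- sn$snapshot$t + 0.3 * sn$stride_period
  dur <- 0.3 * sn$stride_period + 0.4
  und <- run_trial(sn, NULL, p, m, duration = dur)
  mmr <- run_trial(sn, disturbance("mmr", t0 = t0), p, m, duration = dur)
  tr <- mmr$trajectory; un <- und$trajectory[seq_len(nrow(mmr$trajectory)), ]
  d <- tr$sol_r_act - un$sol_r_act
  expect_gt(max(d[tr$time > t0 & tr$time < t0 + 0.08]), 0.02)
  # the response begins only after the 20 ms ankle transport delay
  expect_lt(max(abs(d[tr$time < t0 + 0.019])), 1e-9)
})

test_that("afferent-pulse responses repeat across strides (limit-cycle periodicity)", {
  sn <- fixture_snapshot(0.97)
  p <- fixture_params(0.97); m <- sn$model
  T <- sn$stride_period
  resp <- vapply(0:1, function(k) {
    t0 <- sn$snapshot$t + (0.3 + k) * T
    dur <- (0.3 + k) * T + 0.3
    und <- run_trial(sn, NULL, p, m, duration = dur)
    mmr <- run_trial(sn, disturbance("mmr", t0 = t0), p, m, duration = dur)
    extract_response(.sol_pair(mmr, und), t0, c(0, 0.04))
  }, numeric(1))
  # limit-cycle variability allows moderate stride-to-stride differences
  expect_lt(abs(resp[2] - resp[1]), 0.5 * max(abs(resp)))
})

test_that("tendon taps scale inversely with muscle tension and cap at slack", {
  sn <- fixture_snapshot(0.83)
  p <- fixture_params(0.83); m <- sn$model
  ms <- muscle_set(m)
  # mid-stance: high plantarflexor tension; swing: near-zero tension
  t_st <- sn$snapshot$t + 0.3 * sn$stride_period
  t_sw <- sn$snapshot$t + 0.8 * sn$stride_period
  dur <- 0.8 * sn$stride_period + 0.3
  tap_st <- run_trial(sn, disturbance("tr", t0 = t_st), p, m, duration = dur)
  tap_sw <- run_trial(sn, disturbance("tr", t0 = t_sw), p, m, duration = dur)
  dl_st <- tap_st$disturb_info$tr_dl[1]
  dl_sw <- tap_sw$disturb_info$tr_dl[1]
  expect_gt(dl_sw, dl_st)                   # less tension -> larger stretch
  # doubling the hammer energy doubles the uncapped stretch
  tap2 <- run_trial(sn, disturbance("tr", t0 = t_st, hammer_speed = 1.5 * sqrt(2)),
                    p, m, duration = dur)
  expect_equal(tap2$disturb_info$tr_dl[1], 2 * dl_st, tolerance = 1e-6)
  # a violent tap against the lightly loaded swing tendon hits the stretch cap
  big <- run_trial(sn, disturbance("tr", t0 = t_sw, hammer_speed = 40),
                   p, m, duration = dur)
  expect_equal(big$disturb_info$tr_dl[1], 0.05 * ms$l_opt[ms$muscle == "SOL"],
               tolerance = 1e-9)
  expect_equal(big$disturb_info$tr_capped, 1)
})

test_that("the ankle servo imposes 8 degrees in 32 ms at every phase", {
  sn <- fixture_snapshot(0.97)
  p <- fixture_params(0.97); m <- sn$model
  for (frac in c(0.15, 0.40, 0.65, 0.90)) {
    t0 <- sn$snapshot$t + frac * sn$stride_period
    sr <- run_trial(sn, disturbance("sr", t0 = t0), p, m,
                    duration = frac * sn$stride_period + 0.35)
    tr <- sr$trajectory
    dang <- approx(tr$time, tr$ankle_r, t0 + 0.032)$y -
      approx(tr$time, tr$ankle_r, t0)$y
    expect_equal(dang * 180 / pi, 8, tolerance = 0.2 / 8)
  }
  # the stretch drives soleus lengthening far beyond its stance values
  t0 <- sn$snapshot$t + 0.4 * sn$stride_period
  dur <- 0.4 * sn$stride_period + 0.35
  und <- run_trial(sn, NULL, p, m, duration = dur)
  sr <- run_trial(sn, disturbance("sr", t0 = t0), p, m, duration = dur)
  ramp <- sr$trajectory$time >= t0 & sr$trajectory$time <= t0 + 0.032
  expect_lt(min(sr$trajectory$sol_r_v_ce[ramp]),
            3 * min(und$trajectory$sol_r_v_ce[ramp]))
})

test_that("slips change the stance belt exactly 150 ms after heel strike", {
  sn <- fixture_snapshot(1.20)
  p <- fixture_params(1.20); m <- sn$model
  run <- run_protocol("slip", p, sn, model = m, conditions = c(2, 5))
  info <- run$trials[[1]]$disturb_info
  expect_equal(info$slip_onset - info$slip_hs_time, 0.150, tolerance = 1e-6)
  # larger delta_v -> larger peak foot-vs-belt relative speed
  rel_speed <- function(trial) {
    tr <- trial$trajectory
    sel <- tr$time >= info$slip_onset
    max(abs(tr$dx[sel] - tr$belt_r[sel]))
  }
  expect_gt(rel_speed(run$trials[[2]]), rel_speed(run$trials[[1]]))
  # the belt actually moved by delta_v
  tr <- run$trials[[2]]$trajectory
  expect_equal(min(tr$belt_r), -0.5, tolerance = 1e-9)
})

test_that("trips strike the obstacle near the requested swing fraction", {
  sn <- fixture_snapshot(1.11)
  p <- fixture_params(1.11); m <- sn$model
  run <- run_protocol("trip", p, sn, model = m, conditions = c(2, 6))
  man <- run$manifest
  expect_true(all(man$realizable))
  expect_true(all(diff(man$onset) > 0))    # later condition, later strike
  # a (nearly) massless obstacle barely perturbs the gait
  light <- run_trial(sn, disturbance("trip", mass = 0.02,
                       x_face = run$trials[[1]]$disturbance$x_face),
                     p, m, duration = 2.2 * sn$stride_period)
  heavy <- run$trials[[1]]
  und <- run$undisturbed
  n <- min(nrow(light$trajectory), nrow(und$trajectory))
  d_light <- max(abs(light$trajectory$ta_r_act[seq_len(n)] -
                       und$trajectory$ta_r_act[seq_len(n)]))
  n2 <- min(nrow(heavy$trajectory), nrow(und$trajectory))
  d_heavy <- max(abs(heavy$trajectory$ta_r_act[seq_len(n2)] -
                       und$trajectory$ta_r_act[seq_len(n2)]))
  expect_lt(d_light, d_heavy)
  # an obstacle behind the swing path is flagged unrealizable
  none <- run_trial(sn, disturbance("trip", x_face = 1e6), p, m,
                    duration = 1.5 * sn$stride_period)
  expect_equal(none$disturb_info$trip_hit, 0)
})

test_that("snapshot restarts are deterministic", {
  sn <- fixture_snapshot(0.97)
  p <- fixture_params(0.97); m <- sn$model
  a <- run_trial(sn, NULL, p, m, duration = 0.5)
  b <- run_trial(sn, NULL, p, m, duration = 0.5)
  expect_identical(a$trajectory, b$trajectory)
})
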