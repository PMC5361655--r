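# rigid-body dynamics, contact and integrator properties

wide_model <- function() {
  m <- scale_anthropometry()
  attr(m, "joint_limits") <- rbind(hip = c(-50, 50), knee = c(-50, 50),
                                   ankle = c(-50, 50))
  m
}

pendulum_state <- list(q = c(0, 1.0, pi / 2, 0.5, 0.3, 0.1, -0.4, 0.6, -0.2),
                       qd = rep(0, 9))

test_that("ballistic multi-pendulum conserves mechanical energy to 0.1% per second", {
  sim <- simulate_walk(init = pendulum_state, model = wide_model(),
                       duration = 1, dt = 1e-4, contact = FALSE,
                       muscles = FALSE, pin_base = TRUE,
                       control = "external", stimulations = rep(0, 18))
  E <- sim$trajectory$ke + sim$trajectory$pe
  expect_lt(max(E) - min(E), 0.001 * max(sim$trajectory$ke))
})

test_that("the energy bookkeeping matches independent forward kinematics", {
  m <- wide_model()
  sim <- simulate_walk(init = pendulum_state, model = m, duration = 0.2,
                       dt = 1e-4, contact = FALSE, muscles = FALSE,
                       pin_base = TRUE, control = "external",
                       stimulations = rep(0, 18))
  tr <- sim$trajectory
  i <- 101  # 0.1 s
  q <- as.numeric(tr[i, 2:10])
  pts <- segment_positions(m, q)
  com <- pts[grepl("^com", pts$point), ]
  masses <- c(m$mass[m$segment == "hat"],
              rep(m$mass[m$segment == "thigh_l"], 0))
  # independent potential energy from R-side FK
  mass_of <- c(com_hat = m$mass[m$segment == "hat"],
               com_thigh = m$mass[m$segment == "thigh_l"],
               com_shank = m$mass[m$segment == "shank_l"],
               com_foot = m$mass[m$segment == "foot_l"])
  pe_r <- sum(mass_of[com$point] * 9.81 * com$y)
  expect_equal(pe_r, tr$pe[i], tolerance = 1e-6)
})

test_that("identical configurations give bit-identical trajectories", {
  run <- function() simulate_walk(default_reflex_params(), duration = 2,
                                  v0 = 1.0, record_stride = 20L)
  a <- run(); b <- run()
  expect_identical(a$trajectory, b$trajectory)
  expect_identical(a$events, b$events)
})

test_that("held in zero gravity with zero stimulation, only activations change", {
  # reference posture: every muscle-tendon unit at slack + optimum length,
  # so no passive forces act
  st <- list(q = c(0, 1.0, pi / 2, 0.3, 0.3, 0, 0.3, 0.3, 0), qd = rep(0, 9))
  sim <- simulate_walk(init = st, duration = 0.2, dt = 1e-4, gravity = 0,
                       contact = FALSE, muscles = TRUE, pin_base = TRUE,
                       control = "external", stimulations = rep(0, 18),
                       a0 = 0.2)
  tr <- sim$trajectory
  # activations decay from 0.2 toward 0 ...
  expect_equal(tr$sol_r_act[1], 0.2)
  expect_lt(tail(tr$sol_r_act, 1), 1e-6)
  # ... while a fully quiescent start leaves the pose untouched
  sim0 <- simulate_walk(init = st, duration = 0.2, dt = 1e-4, gravity = 0,
                        contact = FALSE, muscles = TRUE, pin_base = TRUE,
                        control = "external", stimulations = rep(0, 18),
                        a0 = 0)
  tr0 <- sim0$trajectory
  ref <- matrix(rep(c(st$q, st$qd), each = nrow(tr0)), nrow(tr0))
  expect_lt(max(abs(as.matrix(tr0[, 2:19]) - ref)), 1e-12)
})

test_that("airborne feet produce zero contact force", {
  st <- list(q = c(0, 2.0, pi / 2, 0.3, 0.3, 0, -0.3, 0.3, 0), qd = rep(0, 9))
  sim <- simulate_walk(init = st, duration = 0.05, dt = 1e-4,
                       control = "external", stimulations = rep(0.01, 18))
  tr <- sim$trajectory
  expect_true(all(tr[, c("grf_x_l", "grf_y_l", "grf_x_r", "grf_y_r")] == 0))
})

test_that("a static loaded foot on a stationary belt carries no tangential force", {
  m <- scale_anthropometry()
  q <- c(0, 0, pi / 2, 0.02, 0.08, 0, -0.02, 0.08, 0)
  pts <- segment_positions(m, q)
  q[2] <- -min(pts$y[pts$point %in% c("heel", "ball")]) - 3e-3
  sim <- simulate_walk(init = list(q = q, qd = rep(0, 9)), duration = 0.002,
                       dt = 1e-4, record_stride = 1L,
                       control = "external", stimulations = rep(0.01, 18))
  tr <- sim$trajectory
  # zero relative slip at the start; settling only adds microscopic shear
  expect_identical(tr$grf_x_l[2], 0)
  expect_identical(tr$grf_x_r[2], 0)
  expect_lt(max(abs(c(tr$grf_x_l, tr$grf_x_r))),
            0.02 * max(tr$grf_y_l + tr$grf_y_r))
})

test_that("a belt step under a loaded foot drags it backward", {
  m <- scale_anthropometry()
  q <- c(0, 0, pi / 2, 0.02, 0.08, 0, -0.02, 0.08, 0)
  pts <- segment_positions(m, q)
  q[2] <- -min(pts$y[pts$point %in% c("heel", "ball")]) - 2e-3
  sim <- simulate_walk(init = list(q = q, qd = rep(0, 9)), duration = 0.1,
                       dt = 1e-4, ground = ground_model(belt_left = -0.3,
                                                        belt_right = -0.3),
                       control = "external", stimulations = rep(0.01, 18))
  tr <- sim$trajectory
  loaded <- tr$grf_y_l > 50
  expect_lt(mean(tr$grf_x_l[loaded]), 0)   # backward tangential impulse
})

test_that("contact forces respect complementarity and the friction cone", {
  sim <- simulate_walk(default_reflex_params(), duration = 2, v0 = 1.0,
                       record_stride = 10L)
  tr <- sim$trajectory
  expect_true(all(tr$grf_y_l >= 0 & tr$grf_y_r >= 0))
  mu_s <- ground_model()$mu_s
  expect_true(all(abs(tr$grf_x_l) <= mu_s * tr$grf_y_l + 1e-9))
  expect_true(all(abs(tr$grf_x_r) <= mu_s * tr$grf_y_r + 1e-9))
})

test_that("dropping from mid-air is detected as a fall with distance recorded", {
  st <- list(q = c(0, 1.2, pi / 2, 0.3, 1.2, 0, -0.3, 1.2, 0),
             qd = c(0.5, 0, 0, rep(0, 6)))
  sim <- simulate_walk(init = st, duration = 2, control = "external",
                       stimulations = rep(0.01, 18))
  expect_true(sim$fall)
  expect_gte(sim$fall_time, 0)
  expect_true(is.finite(sim$distance))
})
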