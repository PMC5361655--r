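# metabolic energy, the walking cost identity, and the optimizer

make_flat_traj <- function(duration = 2, fs = 100, act = 0, force = 0, vce = 0,
                           muscle = "sol", leg = "r") {
  tm <- seq(0, duration, by = 1 / fs)
  tr <- tibble::tibble(time = tm)
  for (l in c("l", "r")) for (m in tolower(muscle_names())) {
    tr[[paste(m, l, "act", sep = "_")]] <- 0
    tr[[paste(m, l, "force", sep = "_")]] <- 0
    tr[[paste(m, l, "v_ce", sep = "_")]] <- 0
  }
  tr[[paste(muscle, leg, "act", sep = "_")]] <- act
  tr[[paste(muscle, leg, "force", sep = "_")]] <- force
  tr[[paste(muscle, leg, "v_ce", sep = "_")]] <- vce
  tr
}

test_that("quiescent muscles consume nothing; energy is never negative", {
  tr <- make_flat_traj()
  expect_equal(metabolic_energy(tr), 0)
  tr2 <- make_flat_traj(act = 0.3, force = 200, vce = -0.1)  # lengthening
  expect_gt(metabolic_energy(tr2), 0)
})

test_that("a single isometric muscle matches the closed-form rate", {
  ms <- muscle_set()
  a <- 0.4; Tdur <- 2
  tr <- make_flat_traj(duration = Tdur, act = a, muscle = "sol", leg = "r")
  row <- ms[ms$muscle == "SOL", ]
  expected <- 0.5 * a^2 * row$F_max * row$l_opt * Tdur
  expect_equal(metabolic_energy(tr, ms), expected, tolerance = 1e-9)
  # shortening against load adds heat + work: (0.25 + 1) * F * v
  vce <- 0.05
  tr2 <- make_flat_traj(duration = Tdur, act = a, force = 300, vce = vce)
  expect_equal(metabolic_energy(tr2, ms),
               expected + 1.25 * 300 * vce * Tdur, tolerance = 1e-9)
})

test_that("energy is additive: doubling the window doubles the total", {
  tr1 <- make_flat_traj(duration = 2, act = 0.3, force = 150, vce = 0.02)
  tr2 <- make_flat_traj(duration = 4, act = 0.3, force = 150, vce = 0.02)
  expect_equal(2 * metabolic_energy(tr1), metabolic_energy(tr2),
               tolerance = 0.02)
})

test_that("the R energy model agrees with the simulator's bookkeeping", {
  sim <- simulate_walk(default_reflex_params(), duration = 1.0, v0 = 1.0,
                       record_stride = 5L)
  e_cpp <- tail(sim$trajectory$e_met, 1)
  e_r <- metabolic_energy(sim$trajectory)
  expect_equal(e_r, e_cpp, tolerance = 0.02)
})

test_that("the cost identity J = C_E + c_v |v_avg - v_tgt| holds exactly", {
  ct <- suppressWarnings(
    evaluate_cost(default_reflex_params(), v_tgt = 1.0, window = 0.6,
                  transient = 0.2))
  expect_false(ct$fell)
  expect_identical(ct$J, ct$C_E + ct$c_v * abs(ct$v_avg - ct$v_tgt))
  expect_gte(ct$C_E, 0)
  expect_equal(ct$c_v, 100)
})

test_that("fall penalties reward partial progress", {
  fp <- function(d) 1e6 / (1 + max(d, 0))
  expect_lt(fp(5), fp(1))
  expect_true(all(diff(vapply(seq(0, 30, 1), fp, numeric(1))) < 0))
  # and a fall within the evaluation horizon scores worse than any
  # completed walk (stage boundaries in the staged objective)
  expect_gt(fp(25), 2.5e4)
})

test_that("the evolution strategy recovers a quadratic optimum", {
  ctr <- c(0.3, -1.2, 2.0, 0.7, -0.4)
  fn <- function(x) sum((x - ctr)^2)
  res <- cma_es(fn, rep(0, 5), sigma0 = 0.5, budget = 1500, seed = 3)
  expect_lt(sqrt(sum((res$par - ctr)^2)), 1e-3)
  expect_true(all(diff(res$history$best) <= 0))   # best-so-far non-increasing
})

test_that("budget one returns the evaluated initial candidate", {
  fn <- function(x) sum(x^2)
  res <- cma_es(fn, c(1, 1), budget = 1, seed = 5)
  expect_equal(res$par, c(1, 1))
  expect_equal(res$evals, 1)
})

test_that("optimization runs are reproducible from the seed", {
  fn <- function(x) sum((x - 1)^2) + 0.1 * sum(abs(x))
  a <- cma_es(fn, rep(0, 4), budget = 200, seed = 42)
  b <- cma_es(fn, rep(0, 4), budget = 200, seed = 42)
  expect_identical(a$par, b$par)
  expect_identical(a$history, b$history)
  c <- cma_es(fn, rep(0, 4), budget = 200, seed = 43)
  expect_false(identical(a$par, c$par))
})
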