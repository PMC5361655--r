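# delay buffers, gait-event detection, and the reflex network's gating,
# bounds and wiring

test_that("delay buffer returns the sample recorded at t - delay", {
  tm <- seq(0, 1, by = 1e-3)
  const <- tibble::tibble(time = tm, value = rep(3.3, length(tm)))
  expect_equal(delay_buffer_read(const, 0.02, 0.5), 3.3)
  ramp <- tibble::tibble(time = tm, value = tm)
  expect_equal(delay_buffer_read(ramp, 0.03, 0.5), 0.47, tolerance = 1e-9)
  # random sequence against explicit index arithmetic
  set.seed(42)
  rnd <- tibble::tibble(time = tm, value = rnorm(length(tm)))
  for (k in 1:25) {
    d <- sample(0:100, 1) * 1e-3
    t <- sample(200:900, 1) * 1e-3
    idx <- round((t - d) / 1e-3) + 1
    expect_identical(delay_buffer_read(rnd, d, t), rnd$value[idx])
  }
})

test_that("reads before the recorded history fail naming the warm-up span", {
  h <- tibble::tibble(time = seq(0.5, 1, by = 1e-3), value = 0)
  expect_error(delay_buffer_read(h, 0.2, 0.6), "warm up")
})

test_that("gait events land exactly on constructed contact transitions", {
  tm <- seq(0, 3.5, by = 1e-3)
  per <- 1.1; duty <- 0.65
  phase_l <- (tm / per) %% 1
  phase_r <- ((tm + per / 2) / per) %% 1
  hist <- tibble::tibble(time = tm, contact_l = phase_l < duty,
                         contact_r = phase_r < duty)
  gs <- detect_gait_events(hist)
  hs_l <- gs$events$time[gs$events$leg == "l" & gs$events$event == "heel_strike"]
  expect_equal(hs_l, tm[which(diff(phase_l < duty) == 1) + 1])
  to_l <- gs$events$time[gs$events$leg == "l" & gs$events$event == "toe_off"]
  expect_equal(to_l, tm[which(diff(phase_l < duty) == -1) + 1])
  # stride fraction sweeps 0 -> 1 between consecutive heel strikes
  ph <- gs$phases[gs$phases$leg == "l", ]
  btw <- ph$time > hs_l[1] & ph$time < hs_l[1] + per
  sf <- ph$stride_frac[btw]
  expect_true(all(diff(sf) > 0))
  expect_lt(abs(max(sf) - 1), 0.02)
  expect_lt(min(sf), 0.02)
  # exactly one label per leg per instant, changing only at events
  expect_equal(nrow(ph), length(tm))
  expect_true(all(ph$phase %in% c("early_stance", "late_stance", "swing", "late_swing")))
})

test_that("continuous flight yields no events and a warning", {
  hist <- tibble::tibble(time = seq(0, 1, by = 1e-2),
                         contact_l = FALSE, contact_r = FALSE)
  expect_warning(gs <- detect_gait_events(hist), "no contact transitions")
  expect_equal(nrow(gs$events), 0)
})

rest_aff <- function() matrix(0, 18, 3)

test_that("at rest in swing, stimulations sit at their baseline offsets", {
  p <- default_reflex_params()
  s <- compute_stimulations(rest_aff(), list(w_st = c(0, 0), load = c(0, 0)), p)
  # swing pathways see zero afferents; remaining drive is the baseline,
  # clamped from below at stim_min
  expect_true(all(s$stimulation >= 0.01 - 1e-12))
  expect_equal(s$stimulation[s$muscle == "RF"], c(0.01, 0.01))
  expect_equal(s$stimulation[s$muscle == "VAS"],
               rep(unname(p["s0_VAS"]), 2))
})

test_that("a soleus force-afferent step in stance is amplified by exactly the gain", {
  p <- default_reflex_params()
  aff0 <- rest_aff()
  aff0[18, 2] <- 0.9     # give right TA length-afferent drive above threshold
  aff1 <- aff0; aff1[17, 1] <- 0.2   # step the right SOL force afferent
  ph <- list(w_st = c(1, 1), load = c(1, 1))
  s0 <- compute_stimulations(aff0, ph, p)
  s1 <- compute_stimulations(aff1, ph, p)
  d <- s1$stimulation - s0$stimulation
  i_sol_r <- which(s1$muscle == "SOL" & s1$leg == "r")
  expect_equal(d[i_sol_r], unname(p["G_SOL"]) * 0.2, tolerance = 1e-12)
  # and inhibits the antagonist tibialis anterior by exactly its gain
  i_ta_r <- which(s1$muscle == "TA" & s1$leg == "r")
  expect_equal(d[i_ta_r], -unname(p["G_SOLTA"]) * 0.2, tolerance = 1e-12)
  # nothing else on that leg responds to a SOL force afferent
  expect_equal(sum(abs(d) > 1e-15), 2)
})

test_that("identical afferents engage different pathway sets in stance vs swing", {
  p <- default_reflex_params()
  aff <- rest_aff()
  aff[, 1] <- 0.3                       # all force afferents
  aff[, 2] <- 1.0                       # all length afferents at optimum
  st <- compute_stimulations(aff, list(w_st = c(1, 1), load = c(1, 1)), p)
  sw <- compute_stimulations(aff, list(w_st = c(0, 0), load = c(0, 0)), p)
  wiring <- reflex_wiring()
  # force-fed extensors respond in stance only
  for (mus in c("SOL", "GAS", "VAS")) {
    expect_gt(st$stimulation[st$muscle == mus][1],
              sw$stimulation[sw$muscle == mus][1])
    expect_true(all(wiring$phase[wiring$muscle == mus &
                                   wiring$signal == "force"] == "stance"))
  }
  # swing force pathways (HAM) respond in swing
  expect_gt(sw$stimulation[sw$muscle == "HAM"][1], 0.05)
})

test_that("stimulations never leave [stim_min, 1] for any afferent input", {
  p <- default_reflex_params()
  set.seed(7)
  for (i in 1:200) {
    aff <- matrix(runif(54, -3, 3), 18, 3)
    ph <- list(w_st = runif(2), ds = runif(2), swing_frac = runif(2, 0, 1.2),
               lean = runif(1, -1, 1), lean_rate = runif(1, -5, 5),
               load = runif(2), knee = runif(2, -0.2, 2),
               knee_rate = runif(2, -10, 10))
    s <- compute_stimulations(aff, ph, p)
    expect_true(all(s$stimulation >= 0.01 - 1e-12 & s$stimulation <= 1 + 1e-12))
  }
})

test_that("the soleus stance pathway carries no velocity feedback", {
  # structural: the wiring table has no (SOL, velocity) entry
  wiring <- reflex_wiring()
  expect_equal(nrow(wiring[wiring$muscle == "SOL" & wiring$signal == "velocity", ]), 0)
  expect_equal(wiring$signal[wiring$muscle == "SOL" & wiring$phase == "stance"],
               "force")
  # functional: perturbing the velocity afferent alone leaves SOL unchanged
  p <- default_reflex_params()
  ph <- list(w_st = c(1, 1), load = c(1, 1))
  aff0 <- rest_aff(); aff0[17, 1] <- 0.3
  aff1 <- aff0; aff1[17, 3] <- aff1[17, 3] + 5   # huge velocity-afferent change
  s0 <- compute_stimulations(aff0, ph, p)
  s1 <- compute_stimulations(aff1, ph, p)
  expect_identical(s0$stimulation[s0$muscle == "SOL"],
                   s1$stimulation[s1$muscle == "SOL"])
})
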