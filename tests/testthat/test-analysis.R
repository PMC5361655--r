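# response extraction, band normalization, exact band-overlap scaling,
# amplitude ratios, and the velocity-feedback attribution

test_that("extract_response recovers trivial and constructed responses", {
  tm <- seq(0, 0.5, by = 1e-3)
  base <- 0.1 + 0.02 * sin(2 * pi * tm)
  same <- tibble::tibble(time = tm, disturbed = base, undisturbed = base)
  expect_equal(extract_response(same, 0.1, c(0, 0.05)), 0)
  bump <- ifelse(tm >= 0.12 & tm <= 0.14, 0.27, 0)
  tr <- tibble::tibble(time = tm, disturbed = base + bump, undisturbed = base)
  expect_equal(extract_response(tr, 0.1, c(0, 0.08)), 0.27)
  # signed: a negative deflection keeps its sign
  tr2 <- tibble::tibble(time = tm, disturbed = base - bump, undisturbed = base)
  expect_equal(extract_response(tr2, 0.1, c(0, 0.08)), -0.27)
  # mean statistic
  expect_equal(extract_response(tr, 0.1, c(0.02, 0.04), stat = "mean"), 0.27)
})

test_that("noisy responses match a brute-force scan over the window", {
  set.seed(3)
  tm <- seq(0, 0.4, by = 1e-3)
  for (i in 1:20) {
    tr <- tibble::tibble(time = tm, disturbed = rnorm(length(tm)),
                         undisturbed = rnorm(length(tm)))
    onset <- runif(1, 0.05, 0.2); win <- sort(runif(2, 0, 0.15))
    sel <- which(tm >= onset + win[1] & tm <= onset + win[2])
    d <- tr$disturbed[sel] - tr$undisturbed[sel]
    oracle <- 0
    for (v in d) if (abs(v) > abs(oracle)) oracle <- v
    expect_identical(extract_response(tr, onset, win), oracle)
  }
})

test_that("windows outside the trace raise an error", {
  tr <- tibble::tibble(time = seq(0, 0.2, by = 1e-3),
                       disturbed = 0, undisturbed = 0)
  expect_error(extract_response(tr, 0.15, c(0, 0.1)), "window")
})

test_that("normalization divides means and s.d. by the peak mean", {
  b <- normalize_reference(tibble::tibble(condition = 1:2, mean = c(2, 4),
                                          sd = c(1, 1)))
  expect_equal(b$mean, c(0.5, 1))
  expect_equal(b$sd, c(0.25, 0.25))
  expect_error(normalize_reference(tibble::tibble(mean = c(0, 0), sd = c(1, 1))),
               "zero")
})

test_that("normalization is idempotent on random bands", {
  set.seed(11)
  for (i in 1:30) {
    n <- sample(5:16, 1)
    raw <- tibble::tibble(condition = 1:n, mean = rnorm(n) * 10^runif(1, -2, 2),
                          sd = abs(rnorm(n)))
    b1 <- normalize_reference(raw)
    b2 <- normalize_reference(b1)
    expect_equal(b2$mean, b1$mean, tolerance = 1e-12)
    expect_equal(b2$sd, b1$sd, tolerance = 1e-12)
    expect_equal(max(abs(b1$mean)), 1)
  }
})

test_that("scale_to_band recovers exact scalings", {
  mu <- c(0.2, 0.5, 1, 0.7, 0.3)
  band <- tibble::tibble(condition = 1:5, mean = mu, sd = rep(0.1, 5))
  r1 <- scale_to_band(mu, band)
  expect_equal(r1$scale, 1)
  expect_equal(r1$percent, 100)
  # doubled model with bands wide enough: halving recovers full overlap
  r2 <- scale_to_band(2 * mu, band)
  expect_equal(r2$scale, 0.5, tolerance = 1e-9)
  expect_equal(r2$percent, 100)
})

test_that("the constructed 12-of-16 fixture yields exactly 75%", {
  spec <- synth_spec(n_conditions = 16, out_frac = 4 / 16, seed = 5)
  g <- generate_reference_band(spec)
  res <- scale_to_band(g$model_trend, g$band)
  expect_equal(res$n_within, 12)
  expect_equal(res$percent, 75)
  # verified against the dense-grid brute-force maximizer
  bf <- brute_force_overlap(g$model_trend, g$band$mean, g$band$sd)
  expect_equal(res$n_within, bf$count)
})

test_that("exact breakpoint maximizer equals dense-grid brute force on random instances", {
  set.seed(21)
  for (i in 1:400) {
    n <- sample(5:16, 1)
    mu <- rnorm(n)
    mu <- mu / max(abs(mu))
    sd <- abs(rnorm(n, 0.2, 0.1))
    m <- rnorm(n) * 10^runif(1, -1, 1)
    if (runif(1) < 0.2) m[sample(n, 1)] <- 0
    res <- scale_to_band(m, tibble::tibble(condition = 1:n, mean = mu, sd = sd))
    bf <- brute_force_overlap(m, mu, sd)
    expect_equal(res$n_within, bf$count)
    expect_gte(res$scale, 0)
    # reported optimum really achieves the count it claims
    act <- m != 0
    achieved <- sum(abs(res$scale * m[act] - mu[act]) <= sd[act]) +
      sum(!act & abs(mu) <= sd)
    expect_equal(achieved, res$n_within)
  }
})

test_that("overlap is invariant to the reference band's raw units", {
  set.seed(33)
  for (i in 1:25) {
    n <- 12
    raw_mu <- rnorm(n); raw_sd <- abs(rnorm(n, 0.3, 0.1))
    m <- rnorm(n)
    for (scale in c(1, 0.01, 250)) {
      b <- normalize_reference(tibble::tibble(condition = 1:n,
                                              mean = scale * raw_mu,
                                              sd = scale * raw_sd))
      res <- scale_to_band(m, b)
      if (scale == 1) ref <- res$percent
      expect_equal(res$percent, ref)
    }
  }
})

test_that("scale recovery: in-band noise keeps the true scale identifiable", {
  set.seed(8)
  for (k_star in c(0.2, 1, 5)) {
    spec <- synth_spec(n_conditions = 16, k_star = k_star, in_noise = 0.3,
                       sd_rel = 0.25, seed = round(100 * k_star))
    g <- generate_reference_band(spec)
    res <- scale_to_band(g$model_trend, g$band)
    expect_equal(res$percent, 100)
    # k within the band-determined identifiable interval around k_star
    expect_lt(abs(res$scale - k_star) / k_star, 0.5)
  }
})

test_that("amplitude ratios follow direct arithmetic", {
  m <- c(0.1, 0.4, 0.2); r <- c(0.1, 0.4, 0.2)
  expect_equal(amplitude_ratio(m, r), 100)
  expect_equal(amplitude_ratio(0.2 * m, r), 20)
  set.seed(2)
  for (i in 1:20) {
    m <- rnorm(8); r <- rnorm(8)
    mb <- runif(1, 0.1, 2); rb <- runif(1, 0.1, 2)
    oracle <- 100 * (max(abs(m)) / mb) / (max(abs(r)) / rb)
    expect_equal(amplitude_ratio(m, r, mb, rb), oracle)
  }
  expect_error(amplitude_ratio(m, rep(0, 8)), "zero peak")
})

test_that("velocity attribution recovers a constructed composition", {
  # activation built as exactly 45% velocity-proportional + 55% other
  slope <- 0.05
  tm <- seq(0, 1, by = 1e-3)
  v <- pmax(0.8 * sin(2 * pi * tm) + 0.4, 0)          # >= 0 profile
  vel_part <- slope * v
  other <- rep(mean(vel_part) * 55 / 45, length(tm))  # mean-matched remainder
  stance <- tibble::tibble(ankle_vel = v, activation = vel_part + other)
  trials <- tibble::tibble(dvel = c(1, 2, 3, 4, 5),
                           response = slope * c(1, 2, 3, 4, 5))
  res <- velocity_feedback_contribution(trials, stance)
  expect_equal(res$percent, 45, tolerance = 2)
  # zero-slope data attributes nothing
  tr0 <- tibble::tibble(dvel = 1:5, response = rep(0.2, 5))
  expect_equal(velocity_feedback_contribution(tr0, stance)$percent, 0,
               tolerance = 1e-9)
})

test_that("degenerate attribution inputs are rejected", {
  stance <- tibble::tibble(ankle_vel = runif(10), activation = runif(10, 0.1, 0.3))
  expect_error(velocity_feedback_contribution(
    tibble::tibble(dvel = rep(2, 5), response = rnorm(5)), stance), "degenerate")
  expect_error(velocity_feedback_contribution(
    tibble::tibble(dvel = 1:3, response = rnorm(3)), stance), "4")
})
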