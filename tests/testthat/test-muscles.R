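ms <- muscle_set()

test_that("maximum isometric force is exact at optimum length, full activation", {
  for (mus in muscle_names()) {
    row <- ms[ms$muscle == mus, ]
    f <- muscle_force(1, row$l_opt, 0, row)
    expect_identical(f$force, row$F_max)
  }
})

test_that("force scales linearly with activation at optimum, isometric", {
  row <- ms[ms$muscle == "VAS", ]
  f <- muscle_force(0.5, row$l_opt, 0, row)
  expect_equal(f$force, 0.5 * row$F_max)
})

test_that("zero activation leaves only the passive element", {
  row <- ms[ms$muscle == "HAM", ]
  f0 <- muscle_force(0, 1.2 * row$l_opt, 0, row)
  expect_identical(f0$active, 0)
  expect_gt(f0$passive, 0)
  expect_equal(f0$force, f0$passive)
  # below optimum the passive element is slack
  expect_equal(muscle_force(0, 0.9 * row$l_opt, 0.2, row)$force, 0)
})

test_that("force-velocity endpoints: zero at v_max shortening, enhanced eccentric", {
  row <- ms[ms$muscle == "SOL", ]
  expect_equal(muscle_force(1, row$l_opt, row$v_max, row)$force, 0)
  ecc <- muscle_force(1, row$l_opt, -0.3 * row$v_max, row)
  expect_gt(ecc$force, row$F_max)
  expect_lt(ecc$force, 1.5 * row$F_max)
})

test_that("out-of-range activation is clamped with a warning", {
  row <- ms[ms$muscle == "TA", ]
  expect_warning(f <- muscle_force(1.4, row$l_opt, 0, row), "clamped")
  expect_identical(f$force, row$F_max)
})

test_that("moment arms equal the length derivative on a dense angle grid", {
  h <- 1e-6
  for (mus in muscle_names()) {
    row <- ms[ms$muscle == mus, ]
    for (j in 1:3) {
      arm_col <- c("arm_hip", "arm_knee", "arm_ankle")[j]
      if (mtu_kinematics(c(0.2, 0.2, 0.1), row)[[arm_col]] == 0 &&
          mtu_kinematics(c(0.9, 0.9, 0.4), row)[[arm_col]] == 0) next
      grid <- seq(-0.5, 1.2, length.out = 100)
      for (th in grid) {
        ang <- c(0.2, 0.3, 0.1); ang[j] <- th
        up <- ang; up[j] <- th + h
        dn <- ang; dn[j] <- th - h
        num <- (mtu_kinematics(up, row)$length -
                mtu_kinematics(dn, row)$length) / (2 * h)
        arm <- mtu_kinematics(ang, row)[[arm_col]]
        expect_equal(num, arm, tolerance = 1e-6)
      }
    }
  }
})

test_that("monoarticular muscles ignore other joints", {
  row <- ms[ms$muscle == "SOL", ]
  l1 <- mtu_kinematics(c(0.1, 0.2, 0.1), row)$length
  l2 <- mtu_kinematics(c(0.8, 1.1, 0.1), row)$length
  expect_identical(l1, l2)
})

test_that("an ankle dorsiflexion ramp lengthens the soleus throughout", {
  row <- ms[ms$muscle == "SOL", ]
  vel <- 250 * pi / 180
  tt <- seq(0, 8 / 250, length.out = 33)   # 8 deg at 250 deg/s = 32 ms
  v <- vapply(tt, function(t)
    mtu_kinematics(c(0, 0, -0.1 + vel * t), row, c(0, 0, vel))$velocity,
    numeric(1))
  expect_true(all(v > 0))
  # and shortens tibialis anterior
  ta <- ms[ms$muscle == "TA", ]
  vta <- mtu_kinematics(c(0, 0, 0), ta, c(0, 0, vel))$velocity
  expect_lt(vta, 0)
})

test_that("gastrocnemius responds to both knee and ankle rotation", {
  row <- ms[ms$muscle == "GAS", ]
  k <- mtu_kinematics(c(0, 0.3, 0), row)
  base <- k$length
  dknee <- mtu_kinematics(c(0, 0.5, 0), row)$length - base
  dankle <- mtu_kinematics(c(0, 0.3, 0.2), row)$length - base
  expect_true(abs(dknee) > 1e-4 && abs(dankle) > 1e-4)
  expect_lt(dknee, 0)   # knee flexion shortens (knee flexor)
  expect_gt(dankle, 0)  # dorsiflexion stretches (plantarflexor)
})

test_that("muscle constants scale with the body", {
  small <- muscle_set(scale_anthropometry(1.6, 60))
  expect_equal(small$F_max, ms$F_max * 60 / 80)
  expect_equal(small$l_opt, ms$l_opt * 1.6 / 1.8)
  expect_equal(small$v_max, ms$v_max)
})
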