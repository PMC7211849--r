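test_that("fit_wing_plane orients its normal toward the motion direction", {
  wb <- c(0, 0, 0); mj <- c(1, 0, 0); wt <- c(0, 1, 0)
  expect_equal(fit_wing_plane(wb, mj, wt, c(0, 0, 1))$normal, c(0, 0, 1))
  expect_equal(fit_wing_plane(wb, mj, wt, c(0, 0, -1))$normal, c(0, 0, -1))
  expect_error(fit_wing_plane(wb, c(1, 0, 0), c(2, 0, 0), c(0, 0, 1)),
               "collinear")
  expect_error(fit_wing_plane(wb, mj, wt, c(0, 0, 0)), "zero motion")
})

test_that("te_deflection is a normalized signed plane distance", {
  pl <- fit_wing_plane(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  te <- rbind(RP = c(0.5, 0.5, 0), MP = c(0.2, 0.1, 1), CuA = c(0, 0, -2),
              AA = c(3, 3, 0.05))
  d <- te_deflection(pl, te, R = 20)
  expect_equal(unname(d), c(0, 1 / 20, -2 / 20, 0.05 / 20))
  expect_error(te_deflection(pl, te[1:3, ], 20), "missing trailing-edge")

  # invariance under a rigid motion applied jointly to plane and points
  set.seed(8)
  for (i in 1:5) {
    Q <- random_rotation3(); sh <- rnorm(3, 0, 10)
    pl2 <- fit_wing_plane(Q %*% c(0, 0, 0) + sh, Q %*% c(1, 0, 0) + sh,
                          Q %*% c(0, 1, 0) + sh, as.numeric(Q %*% c(0, 0, 1)))
    d2 <- te_deflection(pl2, te %*% t(Q) + rep(1, 4) %*% t(sh), R = 20)
    expect_equal(d2, d, tolerance = 1e-10)
  }
})

test_that("commanded mid-stroke deflections are recovered exactly without noise", {
  amps <- c(RP = 0.04, MP = 0.07, CuA = 0.12, AA = 0.08)
  rec <- simulate_flight(quick_params(te_deflection_amplitudes = amps))
  kin <- wing_angles(rec)
  ms <- midstroke_values(kin, deflection_series(rec))
  expect_lt(max(abs(ms$midstroke_down - amps)), 1e-10)
  expect_lt(max(abs(ms$midstroke_up - amps)), 1e-10)
  # per-cycle values agree for a periodic signal
  per <- ms$per_halfstroke
  for (lm in names(amps)) {
    vals <- per$deflection[per$landmark == lm & per$direction == "down"]
    expect_lt(diff(range(vals)), 1e-10)
  }
  # rigid wing: all mid-stroke values zero
  rec0 <- simulate_flight(quick_params(
    te_deflection_amplitudes = c(RP = 0, MP = 0, CuA = 0, AA = 0)))
  ms0 <- midstroke_values(wing_angles(rec0), deflection_series(rec0))
  expect_lt(max(abs(c(ms0$midstroke_down, ms0$midstroke_up))), 1e-10)
})

test_that("mid-stroke recovery degrades gracefully with digitization noise", {
  amps <- c(RP = 0.04, MP = 0.07, CuA = 0.12, AA = 0.08)
  sg <- 0.05; R <- 20
  errs <- sapply(1:100, function(s) {
    rec <- simulate_flight(flight_sim_params(noise_sigma = sg, seed = s))
    ms <- midstroke_values(wing_angles(rec), deflection_series(rec))
    c(ms$midstroke_down - amps, ms$midstroke_up - amps)
  })
  rmse_by_landmark <- sqrt((rowMeans(errs^2)[1:4] + rowMeans(errs^2)[5:8]) / 2)
  expect_lt(max(rmse_by_landmark), sqrt(2) * sg / R)
  expect_lt(sqrt(mean(errs^2)), sqrt(2) * sg / R)
})

test_that("spanwise_profile interpolates exactly and preserves linearity", {
  span <- c(0.22, 0.42, 0.62, 0.80)
  vals <- c(0.08, 0.12, 0.07, 0.04)
  pr <- spanwise_profile(vals, span)
  expect_equal(pr$fun(span), vals, tolerance = 1e-12)
  # equal values -> flat curve
  flat <- spanwise_profile(rep(0.05, 4), span)
  expect_equal(range(flat$curve$deflection), c(0.05, 0.05))
  # linear values -> linear curve everywhere (Fritsch-Carlson reproduces lines)
  lin <- spanwise_profile(2 * span + 1, span)
  r <- seq(0.22, 0.80, length.out = 41)
  expect_equal(lin$fun(r), 2 * r + 1, tolerance = 1e-10)
  expect_error(spanwise_profile(vals, c(0.2, 0.2, 0.6, 0.8)), "duplicated")
})

test_that("fit_allometry matches a textbook log-log regression", {
  Fv <- c(2e-3, 4e-3, 6e-3, 9e-3)
  beta <- 0.038 * Fv^0.43
  fit <- suppressWarnings(fit_allometry(Fv, beta))
  expect_lt(abs(fit$coefficient_a - 0.038), 1e-10)
  expect_lt(abs(fit$exponent_b - 0.43), 1e-10)
  # constant beta: zero exponent
  f0 <- suppressWarnings(fit_allometry(Fv, rep(0.02, 4)))
  expect_lt(abs(f0$exponent_b), 1e-12)
  expect_error(fit_allometry(c(-1, 2, 3), c(1, 2, 3)), "log transform")
})

test_that("the t-interval of the allometric exponent has nominal coverage", {
  hits <- sapply(1:500, function(s) {
    d <- simulate_allometry(0.038, 0.43, n = 30L, log_noise_sigma = 0.1, seed = s)
    f <- fit_allometry(d$Fv, d$beta)
    f$ci95_b[1L] <= 0.43 && 0.43 <= f$ci95_b[2L]
  })
  expect_gte(mean(hits), 0.93)
  expect_lte(mean(hits), 0.97)
})

test_that("stiffness proxy follows l^3 / beta with EI-ratio consistency", {
  expect_equal(stiffness_proxy(2, 4), 2)
  expect_equal(stiffness_proxy(4, 4), 8 * stiffness_proxy(2, 4))
  expect_error(stiffness_proxy(2, 0), "undeflected")
  # equal load on two wings with EI ratio 3:1 -> deflection ratio 1:3, so
  # the l^3/beta proxy recovers the 3:1 stiffness ratio
  F_load <- 1e-4; l <- 8.4e-3; k <- 3
  beta1 <- F_load * l^3 / (k * 3e-8)
  beta2 <- F_load * l^3 / (k * 1e-8)
  expect_equal(stiffness_proxy(l, beta1) / stiffness_proxy(l, beta2), 3,
               tolerance = 1e-12)
})
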