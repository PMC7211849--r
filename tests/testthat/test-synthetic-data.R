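test_that("simulate_flight is deterministic and validates its inputs", {
  p <- flight_sim_params(noise_sigma = 0.1, seed = 7)
  r1 <- simulate_flight(p)
  r2 <- simulate_flight(p)
  expect_identical(r1$points, r2$points)
  r3 <- simulate_flight(flight_sim_params(noise_sigma = 0.1, seed = 8))
  expect_false(identical(r1$points, r3$points))

  expect_error(flight_sim_params(wing_length_R = 0), "positive")
  expect_error(flight_sim_params(frame_rate = 118 * 10), "undersampled")
  expect_error(flight_sim_params(te_deflection_amplitudes =
                                   c(RP = 0.6, MP = 0, CuA = 0, AA = 0)),
               "\\[0, 0.5\\]")
})

test_that("zero-deflection wings are exactly rigid and planar", {
  rec <- simulate_flight(quick_params(
    te_deflection_amplitudes = c(RP = 0, MP = 0, CuA = 0, AA = 0)))
  R <- rec$params$wing_length_R
  lab <- c("RP", "MP", "CuA", "AA")
  # all TE points lie in the LE plane every frame
  worst <- 0
  for (k in seq_along(rec$times)) {
    wb <- rec$points[k, "wb", ]; mj <- rec$points[k, "mj", ]
    wt <- rec$points[k, "wt", ]
    n <- scarabwing:::unitize(scarabwing:::cross3(mj - wb, wt - wb))
    d <- abs(sweep(rec$points[k, lab, ], 2L, wb, `-`) %*% n)
    worst <- max(worst, d)
  }
  expect_lt(worst, 1e-10 * R)
  # pairwise LE distances constant over time (rigid motion)
  for (pair in list(c("wb", "mj"), c("wb", "wt"), c("mj", "wt"))) {
    d <- sqrt(rowSums((rec$points[, pair[1L], ] - rec$points[, pair[2L], ])^2))
    expect_lt(diff(range(d)) / mean(d), 1e-10)
  }
})

test_that("generated flapping angle has the commanded wingbeat period", {
  rec <- simulate_flight(quick_params(frequency_f = 118))
  phi <- rec$ground_truth$flapping_deg
  rev <- scarabwing:::detect_reversals(rec$times, phi)
  t_max <- rev$times[rev$sense > 0]
  period <- diff(t_max)
  expect_true(all(abs(period - 1 / 118) <= diff(rec$times[1:2])))
})

test_that("Brownian shape radiation matches its analytic moments", {
  # star tree, depth t: across-tip variance of any coordinate ~ sigma2 * t
  tr <- star_tree(500, len = 1.5)
  rad <- simulate_shape_radiation(shape_radiation_params(
    tr, bm_rate_sigma2 = 0.2, n_specimens_per_species = 1L,
    digitization_noise = 0, seed = 9))
  v <- var(rad$species_means[, 5L, 1L])
  truth <- 0.2 * 1.5
  se <- truth * sqrt(2 / 499)
  expect_lt(abs(v - truth), 3 * se)

  # zero rate, zero noise: all tips identical to the ancestor
  rad0 <- simulate_shape_radiation(shape_radiation_params(
    star_tree(6), bm_rate_sigma2 = 0, n_specimens_per_species = 1L,
    digitization_noise = 0, seed = 1))
  expect_equal(max(abs(sweep(rad0$species_means, c(2L, 3L),
                             default_wing_landmarks()))), 0)

  # sister tips on zero-length terminal branches share one shape pre-noise
  tsis <- ape::read.tree(text = "((A:0,B:0):1,C:2);")
  rs <- simulate_shape_radiation(shape_radiation_params(
    tsis, bm_rate_sigma2 = 0.5, n_specimens_per_species = 1L,
    digitization_noise = 0, seed = 3))
  expect_equal(rs$species_means["A", , ], rs$species_means["B", , ])

  expect_error(shape_radiation_params(ape::read.tree(text = "(A,B);")),
               "branch lengths")
})

test_that("tip covariance of a 3-tip radiation matches sigma2 * C", {
  t3 <- ape::read.tree(text = "((A:1,B:1):1,C:2);")
  reps <- sapply(1:500, function(s) {
    simulate_shape_radiation(shape_radiation_params(
      t3, bm_rate_sigma2 = 1, n_specimens_per_species = 1L,
      digitization_noise = 0, seed = s))$species_means[, 1L, 1L]
  })
  Chat <- cov(t(reps))
  C <- bm_covariance(t3, c("A", "B", "C"))
  # elementwise Monte-Carlo tolerance ~ 3 * C_ii * sqrt(2/(n-1))
  expect_lt(max(abs(Chat - C)), 3 * 2 * sqrt(2 / 499))
})

test_that("simulate_bending reproduces the closed-form cantilever force", {
  rec <- simulate_bending(EI = 3e-8, l = 8.4e-3, k = 3, displacement = 1e-3)
  expect_equal(rec$force_F, 3 * 3e-8 * 1e-3 / 8.4e-3^3)
  # linearity in EI
  expect_equal(simulate_bending(6e-8, 8.4e-3)$force_F, 2 * rec$force_F)
  # seeded reproducibility of the noisy force
  f1 <- simulate_bending(3e-8, 8.4e-3, noise_cv = 0.1, seed = 5)$force_F
  f2 <- simulate_bending(3e-8, 8.4e-3, noise_cv = 0.1, seed = 5)$force_F
  expect_identical(f1, f2)
  expect_error(simulate_bending(3e-8, l = 0), "positive")
})

test_that("simulate_allometry round-trips through fit_allometry", {
  d <- simulate_allometry(a = 0.038, b = 0.43, n = 40L, log_noise_sigma = 0,
                          seed = 2)
  fit <- suppressWarnings(fit_allometry(d$Fv, d$beta))
  expect_lt(abs(fit$coefficient_a - 0.038), 1e-10)
  expect_lt(abs(fit$exponent_b - 0.43), 1e-10)

  # b = 0: constant beta
  d0 <- simulate_allometry(a = 0.05, b = 0, n = 10L, seed = 1)
  expect_equal(d0$beta, rep(0.05, 10L))

  # noisy exponent within 3 standard errors at n = 1000
  dn <- simulate_allometry(a = 0.038, b = 0.43, n = 1000L,
                           log_noise_sigma = 0.1, seed = 11)
  fn <- fit_allometry(dn$Fv, dn$beta)
  se <- (fn$ci95_b[2L] - fn$ci95_b[1L]) / (2 * qt(0.975, 998))
  expect_lt(abs(fn$exponent_b - 0.43), 3 * se)

  expect_error(simulate_allometry(n = 2L), "at least 3")
})
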