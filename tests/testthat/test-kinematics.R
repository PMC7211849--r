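test_that("body_frame builds a right-handed triad and is rotation-equivariant", {
  fr <- body_frame(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)))
  expect_equal(fr$axes, diag(3))
  # orthonormal and right-handed for a generic triad
  set.seed(1)
  pts <- matrix(rnorm(9, sd = 5), 3L)
  fr2 <- body_frame(pts)
  expect_equal(crossprod(fr2$axes), diag(3), tolerance = 1e-10)
  expect_equal(det(fr2$axes), 1, tolerance = 1e-10)
  # premultiplying by a known rotation rotates the axes by the same rotation
  for (i in 1:5) {
    Q <- random_rotation3()
    fr3 <- body_frame(pts %*% t(Q))
    expect_equal(fr3$axes, Q %*% fr2$axes, tolerance = 1e-12)
  }
  expect_error(body_frame(rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0))),
               "degenerate thorax triad")
})

test_that("wing_angles inverts the flight simulator exactly on clean data", {
  # estimated stroke plane (planar tip path: zero deviation)
  rec <- simulate_flight(quick_params(deviation_amplitude = 0, seed = 2))
  kin <- wing_angles(rec)
  expect_lt(abs(kin$stroke_plane_deg - 34), 1e-8)
  expect_lt(max(abs(kin$flapping_deg - rec$ground_truth$flapping_deg)), 1e-6)
  expect_lt(max(abs(kin$deviation_deg - rec$ground_truth$deviation_deg)), 1e-6)
  expect_lt(max(abs(kin$incidence_deg - rec$ground_truth$incidence_deg)), 1e-6)

  # with deviation and the stroke plane supplied
  rec2 <- simulate_flight(quick_params(deviation_amplitude = 8, seed = 2))
  kin2 <- wing_angles(rec2, stroke_plane_deg = 34)
  expect_lt(max(abs(kin2$flapping_deg - rec2$ground_truth$flapping_deg)), 1e-6)
  expect_lt(max(abs(kin2$deviation_deg - rec2$ground_truth$deviation_deg)), 1e-6)
  expect_lt(max(abs(kin2$incidence_deg - rec2$ground_truth$incidence_deg)), 1e-6)

  # missing landmark
  broken <- rec
  dimnames(broken$points)[[2]][6] <- "zz"
  expect_error(wing_angles(broken), "missing landmark")
})

test_that("angle reconstruction is equivariant under rigid world motions", {
  rec <- simulate_flight(quick_params(deviation_amplitude = 6,
                                      noise_sigma = 0.02, seed = 4))
  k1 <- wing_angles(rec)
  set.seed(5)
  for (i in 1:3) {
    rec2 <- transform_recording(rec, random_rotation3(), rnorm(3, 0, 15))
    k2 <- wing_angles(rec2)
    expect_lt(max(abs(k1$flapping_deg - k2$flapping_deg)), 1e-8)
    expect_lt(max(abs(k1$deviation_deg - k2$deviation_deg)), 1e-8)
    expect_lt(max(abs(k1$incidence_deg - k2$incidence_deg)), 1e-8)
    expect_lt(abs(k1$stroke_plane_deg - k2$stroke_plane_deg), 1e-8)
    expect_equal(k1$frequency_hz, k2$frequency_hz)
  }
})

test_that("angle recovery error decreases monotonically as noise shrinks", {
  rmse <- sapply(c(0.05, 0.01, 0), function(sg) {
    errs <- sapply(1:5, function(s) {
      r <- simulate_flight(flight_sim_params(noise_sigma = sg, seed = s))
      k <- wing_angles(r, stroke_plane_deg = 34)
      sqrt(mean((k$flapping_deg - r$ground_truth$flapping_deg)^2))
    })
    mean(errs)
  })
  expect_true(all(diff(rmse) < 0))
  expect_lt(rmse[3], 1e-8)
})

test_that("noisy angle RMSE stays within the first-order propagation bound", {
  # leading-order: sigma*sqrt(2) radians per unit baseline, wing (R = 20 mm)
  # plus thorax triad (shortest edge 5 mm) contributions
  sg <- 0.05
  bound_deg <- (180 / pi) * sg * sqrt(2) * (1 / 20 + 1 / 5)
  errs <- sapply(1:30, function(s) {
    r <- simulate_flight(flight_sim_params(noise_sigma = sg, seed = s))
    k <- wing_angles(r, stroke_plane_deg = 34)
    sqrt(mean((k$flapping_deg - r$ground_truth$flapping_deg)^2))
  })
  expect_lt(sqrt(mean(errs^2)), 3 * bound_deg)
})

test_that("wingbeat frequency is recovered without bias on clean sinusoids", {
  for (f in c(50, 109, 118, 200)) {
    rec <- simulate_flight(quick_params(frequency_f = f, frame_rate = 5000))
    kin <- wing_angles(rec)
    # quantization bound: one frame interval over the measured span
    expect_lt(abs(kin$frequency_hz - f), f^2 / 5000 / 2)
    expect_equal(wingbeat_frequency(kin), kin$frequency_hz)
  }
  # halving the frame rate keeps the estimate within quantization
  rec <- simulate_flight(quick_params(frequency_f = 118, frame_rate = 2500))
  expect_lt(abs(wing_angles(rec)$frequency_hz - 118), 118^2 / 2500)
  # constant angle: no reversals
  expect_error(scarabwing:::detect_reversals(1:50 / 50, seq(0, 1, length.out = 50)),
               "no reversals")
})

test_that("stroke_plane recovers known plane inclinations", {
  for (gamma in c(0, 30, 90)) {
    rec <- simulate_flight(quick_params(stroke_plane_angle = gamma,
                                        deviation_amplitude = 0))
    kin <- wing_angles(rec, stroke_plane_deg = gamma)
    expect_lt(abs(stroke_plane(kin) - gamma), 0.1)
  }
})

test_that("advance ratio and vertical force follow their defining formulas", {
  expect_equal(advance_ratio(0, 2, 100, 0.02), 0)
  expect_equal(advance_ratio(0.4, 120 * pi / 180, 100, 0.02),
               0.4 / (2 * 120 * pi / 180 * 100 * 0.02))
  expect_lt(advance_ratio(0.4, 120 * pi / 180, 100, 0.02), 0.1)  # hovering regime
  expect_equal(advance_ratio(0.4, 2, 200, 0.02),
               advance_ratio(0.4, 2, 100, 0.02) / 2)
  expect_error(advance_ratio(0.4, 2, 0, 0.02), "positive")

  expect_equal(vertical_force(0.908e-3, 0), 0.908e-3 * 9.81)
  expect_equal(vertical_force(1, -9.81), 0)
  expect_equal(vertical_force(1, 0.19), 10)
  expect_error(vertical_force(0), "positive")
})
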