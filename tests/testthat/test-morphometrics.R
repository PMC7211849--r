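make_perturbed_set <- function(n = 10L, sd = 0.15, seed = 42) {
  base <- default_wing_landmarks()
  set.seed(seed)
  arr <- array(NA_real_, c(n, 25L, 2L))
  for (i in seq_len(n)) arr[i, , ] <- base + matrix(rnorm(50, 0, sd), 25L, 2L)
  shape_set(arr)
}

test_that("GPA removes similarity transforms exactly", {
  shapes <- make_perturbed_set()
  a1 <- gpa(shapes)
  # aligned configurations are centred with unit centroid size
  for (i in 1:dim(a1$aligned)[1]) {
    expect_lt(max(abs(colMeans(a1$aligned[i, , ]))), 1e-10)
    expect_equal(sum(a1$aligned[i, , ]^2), 1, tolerance = 1e-10)
  }
  expect_equal(apply(a1$aligned, c(2, 3), mean) /
                 sqrt(sum(apply(a1$aligned, c(2, 3), mean)^2)),
               a1$mean_shape, tolerance = 1e-8)

  # random per-specimen similarity transforms leave the output unchanged
  set.seed(7)
  arr2 <- shapes$configurations
  for (i in 1:dim(arr2)[1]) arr2[i, , ] <- similarity_transform2(arr2[i, , ])
  a2 <- gpa(shape_set(arr2))
  expect_lt(max(abs(a1$aligned - a2$aligned)), 1e-8)
  expect_lt(max(abs(a1$mean_shape - a2$mean_shape)), 1e-8)
})

test_that("copies of one shape collapse to zero Procrustes distance", {
  base <- default_wing_landmarks()
  set.seed(3)
  arr <- array(NA_real_, c(6L, 25L, 2L))
  for (i in 1:6) arr[i, , ] <- similarity_transform2(base)
  a <- gpa(shape_set(arr))
  expect_lt(max(a$procrustes_distances), 1e-10)
  # two shapes differing by pure scaling
  arr2 <- array(NA_real_, c(2L, 25L, 2L))
  arr2[1, , ] <- base; arr2[2, , ] <- 3.7 * base
  expect_lt(max(gpa(shape_set(arr2))$procrustes_distances), 1e-10)
  # degenerate configuration
  bad <- array(0, c(2L, 25L, 2L)); bad[1, , ] <- base
  expect_error(gpa(shape_set(bad)), "degenerate")
})

test_that("GPA recovers a constructed mean from small tangent perturbations", {
  base <- default_wing_landmarks()
  M0 <- sweep(base, 2L, colMeans(base))
  M0 <- M0 / sqrt(sum(M0^2))
  M0 <- M0 %*% scarabwing:::canonical_rotation(M0)
  set.seed(11)
  n <- 20L
  pert <- array(rnorm(n * 50, 0, 1e-4), c(n, 25L, 2L))
  pert <- sweep(pert, c(2L, 3L), apply(pert, c(2L, 3L), mean))  # mean-zero
  arr <- array(NA_real_, c(n, 25L, 2L))
  for (i in seq_len(n)) arr[i, , ] <- M0 + pert[i, , ]
  a <- gpa(shape_set(arr))
  expect_lt(max(abs(a$mean_shape - M0)), 1e-6)
})

test_that("shape PCA recovers a planted group-separation axis", {
  base <- default_wing_landmarks()
  v <- rnorm(50); v <- v / sqrt(sum(v^2))
  set.seed(21)
  arr <- array(NA_real_, c(30L, 25L, 2L))
  for (i in 1:30) {
    shift <- if (i <= 15) 0.4 else -0.4
    flat <- as.numeric(base) + shift * v + rnorm(50, 0, 0.02)
    arr[i, , ] <- matrix(flat, 25L, 2L)
  }
  # plain matrix interface: rows are flattened configurations, and the
  # loadings come back in the same (column-major) coordinate order as v
  sp <- shape_pca(matrix(arr, 30L, 50L))
  pc1 <- sp$loadings[1L, ]
  expect_gt(abs(sum(pc1 * v)), 0.99)
  expect_equal(sum(sp$percent_variance), 100, tolerance = 1e-8)

  # identical specimens: no variation
  same <- matrix(rep(as.numeric(base), 4), 4L, 50L, byrow = TRUE)
  expect_error(shape_pca(same), "rank-0")
})

test_that("PCA scores are uncorrelated and eigenvalues ordered", {
  a <- gpa(make_perturbed_set(n = 15L))
  sp <- shape_pca(a)
  G <- crossprod(sp$scores[, 1:8])
  expect_lt(max(abs(G - diag(diag(G)))), 1e-8)
  expect_true(all(diff(sp$eigenvalues) <= 1e-12))
})

test_that("landmark contributions decompose a loading vector", {
  v <- rep(0, 50); v[2 * 7 - 1] <- 0.6; v[2 * 7] <- 0.8  # all on landmark 7
  ct <- landmark_contributions(v)
  expect_equal(unname(ct[7]), 100)
  expect_equal(sum(ct), 100)
  # uniform loadings: 4% per landmark
  expect_equal(unname(landmark_contributions(rep(1, 50))),
               rep(4, 25), tolerance = 1e-12)
  expect_error(landmark_contributions(rep(0, 50)), "zero loading")
})

test_that("radiations with localized clade offsets surface those landmarks", {
  off <- matrix(0, 25L, 2L)
  off[22L, ] <- c(0.9, -0.7)
  off[25L, ] <- c(-0.8, 0.8)
  hits <- sapply(1:25, function(s) {
    tree <- scarabwing:::with_private_seed(s,
      ape::rcoal(20L, tip.label = sprintf("sp%02d", 1:20)))
    tree$edge.length <- tree$edge.length / max(ape::node.depth.edgelength(tree))
    clade <- scarabwing:::larger_root_clade(tree)
    rad <- simulate_shape_radiation(shape_radiation_params(
      tree, bm_rate_sigma2 = 0.02, n_specimens_per_species = 5L,
      digitization_noise = 0.05, seed = s,
      clade_offsets = list(list(tips = clade, offset = off))))
    ct <- landmark_contributions(shape_pca(gpa(rad))$loadings[1L, ])
    identical(sort(order(ct, decreasing = TRUE)[1:2]), c(22L, 25L))
  })
  expect_gte(mean(hits), 0.95)
})
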