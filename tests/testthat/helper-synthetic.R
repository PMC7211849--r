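# Shared fixtures built in code: quick simulator parameter sets and random
# rigid/similarity transforms used by the invariance tests.

quick_params <- function(...) {
  args <- list(n_cycles = 3, noise_sigma = 0)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(flight_sim_params, args)
}

rotation3 <- function(axis, angle) scarabwing:::rotation_about(axis, angle)

random_rotation3 <- function() {
  ax <- stats::rnorm(3)
  rotation3(ax, stats::runif(1, 0, 2 * pi))
}

rotation2 <- function(theta) {
  matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2L, 2L)
}

# Apply a rigid world transform to every frame of a flight recording.
transform_recording <- function(rec, Q = diag(3), shift = c(0, 0, 0)) {
  out <- rec
  n <- dim(rec$points)[2L]
  for (k in seq_along(rec$times)) {
    out$points[k, , ] <- rec$points[k, , ] %*% t(Q) + rep(1, n) %*% t(shift)
  }
  out
}

# Random similarity transform (rotation + scale + translation) of a 2D
# landmark configuration.
similarity_transform2 <- function(conf) {
  th <- stats::runif(1, 0, 2 * pi)
  s <- exp(stats::runif(1, -1, 1))
  tr <- stats::rnorm(2, 0, 20)
  s * conf %*% rotation2(th) + rep(1, nrow(conf)) %*% t(tr)
}

star_tree <- function(n, len = 1, labels = sprintf("t%03d", seq_len(n))) {
  tr <- ape::stree(n, "star")
  tr$edge.length <- rep(len, n)
  tr$tip.label <- labels
  tr
}
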