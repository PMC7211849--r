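# Landmark configurations are n x k x 2 arrays (specimens, landmarks, x/y).

#' Construct a set of 2D landmark configurations
#'
#' @param configurations n x k x 2 array of landmark coordinates.
#' @param specimen_ids character vector of length n.
#' @param species character vector of length n (species label per specimen).
#' @return Object of class `shape_set`.
#' @export
shape_set <- function(configurations,
                      specimen_ids = sprintf("spec%03d", seq_len(dim(configurations)[1L])),
                      species = rep("sp", dim(configurations)[1L])) {
  stopifnot(length(dim(configurations)) == 3L, dim(configurations)[3L] == 2L)
  if (anyNA(configurations)) stop("missing coordinates in landmark data", call. = FALSE)
  n <- dim(configurations)[1L]
  stopifnot(length(specimen_ids) == n, length(species) == n)
  out <- list(configurations = configurations,
              specimen_ids = as.character(specimen_ids),
              species = as.character(species))
  class(out) <- "shape_set"
  out
}

#' @export
print.shape_set <- function(x, ...) {
  d <- dim(x$configurations)
  cat(sprintf("<shape_set> %d specimens x %d landmarks (2D), %d species\n",
              d[1L], d[2L], length(unique(x$species))))
  invisible(x)
}

centroid_size <- function(conf) {
  ctr <- colMeans(conf)
  sqrt(sum(sweep(conf, 2L, ctr, `-`)^2))
}

# Optimal rotation (no reflection) aligning X to M (both k x 2, centred):
# returns the 2 x 2 rotation R minimizing ||X R - M||.
kabsch2 <- function(X, M) {
  sv <- svd(crossprod(X, M))
  d <- sign(det(sv$u %*% t(sv$v)))
  sv$u %*% diag(c(1, d)) %*% t(sv$v)
}

# Canonical orientation: rotate the aligned set so the mean shape's major
# principal axis lies along x, with the sign fixed by the third moment of
# the coordinates (falls back to y if the x moment is degenerate). Makes
# GPA output strictly invariant to similarity transforms of the input.
canonical_rotation <- function(mean_shape) {
  sv <- svd(sweep(mean_shape, 2L, colMeans(mean_shape), `-`))
  Q <- sv$v
  if (det(Q) < 0) Q[, 2L] <- -Q[, 2L]
  m <- mean_shape %*% Q
  s3 <- sum(m[, 1L]^3)
  if (abs(s3) < 1e-12 * max(abs(m))^3) s3 <- sum(m[, 2L]^3)
  if (s3 < 0) Q <- -Q
  Q
}

#' Generalized Procrustes alignment of 2D landmark configurations
#'
#' Full GPA: each configuration is translated to a common centroid, scaled
#' to unit centroid size, and iteratively rotated (rotation only, no
#' reflection) onto the evolving mean shape until the mean changes by less
#' than `tol`. The first configuration initializes the mean; after
#' convergence the whole set is put in a canonical orientation so the
#' result does not depend on the pose of the inputs.
#'
#' @param shapes a [shape_set()] (or bare n x k x 2 array).
#' @param tol convergence tolerance on the mean shape.
#' @param max_iter iteration cap.
#' @return Object of class `aligned_shapes`: `aligned` (n x k x 2, each with
#'   centroid at the origin and unit centroid size), `mean_shape` (k x 2),
#'   `centroid_sizes` and `procrustes_distances` per specimen, plus the
#'   specimen/species labels.
#' @export
gpa <- function(shapes, tol = 1e-10, max_iter = 200L) {
  if (is.array(shapes) && !inherits(shapes, "shape_set")) shapes <- shape_set(shapes)
  conf <- shapes$configurations
  n <- dim(conf)[1L]; k <- dim(conf)[2L]
  if (n < 2L) stop("need at least 2 configurations", call. = FALSE)
  if (k < 3L) stop("need at least 3 landmarks", call. = FALSE)

  sizes <- numeric(n)
  X <- conf
  for (i in seq_len(n)) {
    ci <- conf[i, , ]
    ctr <- colMeans(ci)
    ci <- sweep(ci, 2L, ctr, `-`)
    cs <- sqrt(sum(ci^2))
    if (cs < 1e-12) stop("degenerate configuration: all landmarks coincident",
                         call. = FALSE)
    sizes[i] <- cs
    X[i, , ] <- ci / cs
  }

  M <- X[1L, , ]
  for (iter in seq_len(max_iter)) {
    for (i in seq_len(n)) {
      X[i, , ] <- X[i, , ] %*% kabsch2(X[i, , ], M)
    }
    Mnew <- apply(X, c(2L, 3L), mean)
    Mnew <- Mnew / sqrt(sum(Mnew^2))
    delta <- sqrt(sum((Mnew - M)^2))
    M <- Mnew
    if (delta < tol) break
  }

  Q <- canonical_rotation(M)
  M <- M %*% Q
  for (i in seq_len(n)) X[i, , ] <- X[i, , ] %*% Q

  pd <- sqrt(apply(sweep(X, c(2L, 3L), M, `-`)^2, 1L, sum))
  out <- list(aligned = X, mean_shape = M, centroid_sizes = sizes,
              procrustes_distances = pd,
              specimen_ids = shapes$specimen_ids, species = shapes$species)
  class(out) <- "aligned_shapes"
  out
}

#' @export
print.aligned_shapes <- function(x, ...) {
  d <- dim(x$aligned)
  cat(sprintf("<aligned_shapes> %d specimens x %d landmarks; max Procrustes distance %.3g\n",
              d[1L], d[2L], max(x$procrustes_distances)))
  invisible(x)
}

# Flatten n x k x 2 -> n x 2k with columns x1, y1, x2, y2, ...
flatten_shapes <- function(arr) {
  n <- dim(arr)[1L]; k <- dim(arr)[2L]
  out <- matrix(NA_real_, n, 2L * k)
  out[, seq(1L, 2L * k, by = 2L)] <- arr[, , 1L]
  out[, seq(2L, 2L * k, by = 2L)] <- arr[, , 2L]
  colnames(out) <- as.vector(rbind(paste0("x", seq_len(k)), paste0("y", seq_len(k))))
  out
}

unflatten_shapes <- function(mat) {
  k <- ncol(mat) / 2L
  arr <- array(NA_real_, c(nrow(mat), k, 2L))
  arr[, , 1L] <- mat[, seq(1L, 2L * k, by = 2L)]
  arr[, , 2L] <- mat[, seq(2L, 2L * k, by = 2L)]
  arr
}

# Deterministic eigenvector sign: largest-magnitude element positive.
fix_eigen_signs <- function(V) {
  for (j in seq_len(ncol(V))) {
    i <- which.max(abs(V[, j]))
    if (V[i, j] < 0) V[, j] <- -V[, j]
  }
  V
}

#' Principal component analysis of aligned shapes
#'
#' Eigen-decomposition of the covariance matrix of the mean-centred aligned
#' coordinates (specimens as rows, 2k columns). Eigenvector signs are fixed
#' deterministically (largest-magnitude element positive).
#'
#' @param aligned an [gpa()] result (or a plain specimens x coordinates
#'   matrix).
#' @return Object of class `shape_space`: `eigenvalues`, `percent_variance`,
#'   `scores` (specimens x PC), `loadings` (PC x 2k), `center` and labels.
#' @export
shape_pca <- function(aligned) {
  X <- if (inherits(aligned, "aligned_shapes")) flatten_shapes(aligned$aligned) else
    as.matrix(aligned)
  if (nrow(X) < 3L) stop("need at least 3 specimens", call. = FALSE)
  ctr <- colMeans(X)
  Xc <- sweep(X, 2L, ctr, `-`)
  S <- crossprod(Xc) / (nrow(X) - 1L)
  ee <- eigen((S + t(S)) / 2, symmetric = TRUE)
  ev <- pmax(ee$values, 0)
  if (sum(ev) <= 0) stop("rank-0 shape data: no variation among specimens",
                         call. = FALSE)
  V <- fix_eigen_signs(ee$vectors)
  scores <- Xc %*% V
  colnames(scores) <- paste0("PC", seq_len(ncol(scores)))
  out <- list(eigenvalues = ev,
              percent_variance = 100 * ev / sum(ev),
              scores = scores,
              loadings = t(V),
              center = ctr,
              specimen_ids = if (inherits(aligned, "aligned_shapes")) aligned$specimen_ids,
              species = if (inherits(aligned, "aligned_shapes")) aligned$species)
  class(out) <- "shape_space"
  out
}

#' @export
print.shape_space <- function(x, ...) {
  cat(sprintf("<shape_space> %d specimens; PC1 %.1f%%, PC2 %.1f%% of variance\n",
              nrow(x$scores), x$percent_variance[1L],
              if (length(x$percent_variance) > 1L) x$percent_variance[2L] else 0))
  invisible(x)
}

#' @export
plot.shape_space <- function(x, pcs = c(1L, 2L), ...) {
  grp <- if (!is.null(x$species)) factor(x$species) else factor(rep(1, nrow(x$scores)))
  graphics::plot(x$scores[, pcs], col = as.integer(grp), pch = 19,
                 xlab = sprintf("PC%d (%.1f%%)", pcs[1L], x$percent_variance[pcs[1L]]),
                 ylab = sprintf("PC%d (%.1f%%)", pcs[2L], x$percent_variance[pcs[2L]]),
                 ...)
  invisible(x)
}

#' Per-landmark contribution to a principal component
#'
#' Shares of the squared loading vector summed over the x and y coordinate
#' of each landmark: `100 * (v_xi^2 + v_yi^2) / sum_j (v_xj^2 + v_yj^2)`.
#'
#' @param loading_vector numeric vector of length 2k (x/y interleaved, as in
#'   the rows of `shape_space$loadings`).
#' @return Named vector of percentages summing to 100.
#' @export
landmark_contributions <- function(loading_vector) {
  v <- as.numeric(loading_vector)
  if (length(v) %% 2L != 0L) stop("loading vector must have 2 coordinates per landmark",
                                  call. = FALSE)
  tot <- sum(v^2)
  if (tot == 0) stop("zero loading vector", call. = FALSE)
  k <- length(v) / 2L
  per <- v[seq(1L, 2L * k, by = 2L)]^2 + v[seq(2L, 2L * k, by = 2L)]^2
  stats::setNames(100 * per / tot, paste0("lm", seq_len(k)))
}
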