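#' Thin-plate-spline warp between two landmark configurations
#'
#' Standard 2D thin-plate spline with kernel `U(r) = r^2 log(r)`
#' (`U(0) = 0`) and side conditions annihilating the affine terms. The warp
#' interpolates every source landmark to its target exactly; the bending
#' energy `trace(W' K W)` is zero exactly when the map is affine.
#'
#' @param source,target k x 2 matrices of matching landmarks; source
#'   landmarks must be pairwise distinct.
#' @return Object of class `tps_warp`: `affine_part` (2 x 3: translation
#'   column followed by the linear map), `kernel_weights` (k x 2),
#'   `bending_energy`, and `warp`, a function mapping an m x 2 matrix (or a
#'   length-2 point) through the spline.
#' @export
tps_warp <- function(source, target) {
  source <- as.matrix(source); target <- as.matrix(target)
  stopifnot(ncol(source) == 2L, ncol(target) == 2L, nrow(source) == nrow(target))
  k <- nrow(source)
  if (k < 3L) stop("need at least 3 landmarks", call. = FALSE)
  D <- as.matrix(stats::dist(source))
  if (min(D[upper.tri(D)]) < 1e-12 * max(D)) {
    stop("singular kernel system: coincident source landmarks", call. = FALSE)
  }
  K <- tps_kernel(D)
  P <- cbind(1, source)
  L <- rbind(cbind(K, P), cbind(t(P), matrix(0, 3L, 3L)))
  sol <- solve(L, rbind(target, matrix(0, 3L, 2L)))
  W <- sol[seq_len(k), , drop = FALSE]
  A <- sol[k + 1:3, , drop = FALSE]          # 3 x 2: rows = (1, x, y) coeffs
  be <- max(0, sum(diag(crossprod(W, K %*% W))))

  src <- source
  warp <- function(pts) {
    pts <- if (is.null(dim(pts))) matrix(pts, ncol = 2L) else as.matrix(pts)
    U <- tps_kernel(cdist2(pts, src))
    pts %*% A[2:3, , drop = FALSE] + rep(1, nrow(pts)) %*% A[1L, , drop = FALSE] +
      U %*% W
  }

  out <- list(affine_part = t(A),           # 2 x 3 (translation | linear map)
              kernel_weights = W,
              bending_energy = be,
              warp = warp,
              source = source, target = target)
  class(out) <- "tps_warp"
  out
}

tps_kernel <- function(r) {
  U <- r^2 * log(ifelse(r > 0, r, 1))
  U[r == 0] <- 0
  U
}

# Pairwise Euclidean distances between rows of a (m x 2) and b (k x 2).
cdist2 <- function(a, b) {
  m <- nrow(a); k <- nrow(b)
  dx <- outer(a[, 1L], b[, 1L], `-`)
  dy <- outer(a[, 2L], b[, 2L], `-`)
  sqrt(dx * dx + dy * dy)
}

#' @export
print.tps_warp <- function(x, ...) {
  cat(sprintf("<tps_warp> %d landmarks; bending energy %.4g\n",
              nrow(x$source), x$bending_energy))
  invisible(x)
}

#' Deformation grid of a thin-plate-spline warp
#'
#' Maps a regular grid through the warp for visualization of local
#' contraction and expansion between the two configurations.
#'
#' @param warp a [tps_warp()].
#' @param bounds list or vector `c(xmin, xmax, ymin, ymax)`; defaults to the
#'   source landmark range expanded by 10%.
#' @param n_grid number of grid lines per direction.
#' @param n_samples points sampled along each grid line.
#' @return `data.frame` with columns `line_id`, `orientation`
#'   (`"h"`/`"v"`), and warped `x`, `y`, ready for line plotting.
#' @export
deformation_grid <- function(warp, bounds = NULL, n_grid = 10L, n_samples = 50L) {
  stopifnot(inherits(warp, "tps_warp"))
  if (is.null(bounds)) {
    rx <- range(warp$source[, 1L]); ry <- range(warp$source[, 2L])
    ex <- 0.1 * diff(rx); ey <- 0.1 * diff(ry)
    bounds <- c(rx[1L] - ex, rx[2L] + ex, ry[1L] - ey, ry[2L] + ey)
  }
  xs <- seq(bounds[1L], bounds[2L], length.out = n_grid)
  ys <- seq(bounds[3L], bounds[4L], length.out = n_grid)
  sx <- seq(bounds[1L], bounds[2L], length.out = n_samples)
  sy <- seq(bounds[3L], bounds[4L], length.out = n_samples)
  rows <- list()
  for (i in seq_along(ys)) {   # horizontal lines
    w <- warp$warp(cbind(sx, ys[i]))
    rows[[length(rows) + 1L]] <- data.frame(line_id = i, orientation = "h",
                                            x = w[, 1L], y = w[, 2L])
  }
  for (i in seq_along(xs)) {   # vertical lines
    w <- warp$warp(cbind(xs[i], sy))
    rows[[length(rows) + 1L]] <- data.frame(line_id = i, orientation = "v",
                                            x = w[, 1L], y = w[, 2L])
  }
  do.call(rbind, rows)
}

#' @export
plot.tps_warp <- function(x, n_grid = 12L, ...) {
  g <- deformation_grid(x, n_grid = n_grid)
  graphics::plot(g$x, g$y, type = "n", asp = 1, xlab = "", ylab = "", ...)
  for (o in c("h", "v")) for (i in unique(g$line_id)) {
    sub <- g[g$orientation == o & g$line_id == i, ]
    graphics::lines(sub$x, sub$y, col = "grey60")
  }
  graphics::points(x$target, pch = 19, col = "darkgreen")
  graphics::arrows(x$source[, 1L], x$source[, 2L], x$target[, 1L], x$target[, 2L],
                   length = 0.05, col = "blue")
  invisible(x)
}
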