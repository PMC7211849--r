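#' Rigid leading-edge plane of a single frame
#'
#' Plane through the three leading-edge landmarks, with the unit normal
#' flipped toward the instantaneous wing-motion direction so that positive
#' perpendicular offsets point to the pressure side of the wing.
#'
#' @param wb,mj,wt 3-vectors (same units).
#' @param motion_direction nonzero 3-vector giving the instantaneous motion
#'   of the wing; only its sign relative to the plane normal is used.
#' @return List with `anchor` (wb) and oriented `normal` (unit 3-vector).
#' @export
fit_wing_plane <- function(wb, mj, wt, motion_direction) {
  nr <- cross3(mj - wb, wt - wb)
  scale2 <- max(sum((mj - wb)^2), sum((wt - wb)^2))
  if (scale2 == 0 || vnorm(nr) < 1e-10 * scale2) {
    stop("collinear leading-edge landmarks: wing plane undefined", call. = FALSE)
  }
  if (vnorm(motion_direction) == 0) {
    stop("zero motion vector: cannot orient the wing-plane normal", call. = FALSE)
  }
  n <- unitize(nr)
  if (sum(n * motion_direction) < 0) n <- -n
  list(anchor = wb, normal = n)
}

#' Normalized signed trailing-edge deflections for one frame
#'
#' Signed perpendicular distance of each trailing-edge landmark from the
#' leading-edge plane, divided by wing length. Positive values point toward
#' the plane's oriented normal (the pressure side).
#'
#' @param plane a [fit_wing_plane()] result.
#' @param te_points 4 x 3 matrix with rownames RP, MP, CuA, AA.
#' @param R wing length in the same units as the coordinates.
#' @return Named numeric vector of dimensionless deflections.
#' @export
te_deflection <- function(plane, te_points, R) {
  stopifnot_scalar_pos(R, "R")
  te_points <- as.matrix(te_points)
  need <- c("RP", "MP", "CuA", "AA")
  miss <- setdiff(need, rownames(te_points))
  if (length(miss)) stop("missing trailing-edge landmark(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  d <- sweep(te_points[need, , drop = FALSE], 2L, plane$anchor, `-`) %*% plane$normal
  stats::setNames(as.numeric(d) / R, need)
}

#' Trailing-edge deflection time series from a flight recording
#'
#' For every frame, expresses the wing landmarks in the body frame, fits the
#' rigid leading-edge plane (wb, mj, wt), orients its normal toward the
#' instantaneous motion of the trailing-edge centroid (central differences;
#' when the wing is nearly stationary at stroke reversal the previous
#' orientation is kept), and records the wing-length-normalized signed
#' deflection of RP, MP, CuA and AA.
#'
#' @param recording a `flight_recording`.
#' @param R wing length (mm); estimated as the mean wb-wt distance when
#'   `NULL`.
#' @param freeze_speed threshold, in wing lengths per frame, below which the
#'   plane orientation is frozen from the previous frame.
#' @return Object of class `deflection_series` with `times`, `deflections`
#'   (frames x 4) and `wing_length_R`.
#' @export
deflection_series <- function(recording, R = NULL, freeze_speed = 1e-6) {
  pts <- recording$points
  times <- recording$times
  lab <- c("RP", "MP", "CuA", "AA")
  need <- c("th1", "th2", "th3", "wb", "mj", "wt", lab)
  miss <- setdiff(need, dimnames(pts)[[2L]])
  if (length(miss)) stop("missing landmark(s): ", paste(miss, collapse = ", "),
                         call. = FALSE)
  nfr <- dim(pts)[1L]

  wing <- array(NA_real_, c(nfr, 7L, 3L), dimnames = list(NULL, need[-(1:3)], NULL))
  for (k in seq_len(nfr)) {
    fr <- body_frame(pts[k, c("th1", "th2", "th3"), ])
    wing[k, , ] <- to_body_coords(pts[k, need[-(1:3)], ], fr)
  }
  if (is.null(R)) {
    R <- mean(sqrt(rowSums((wing[, "wt", ] - wing[, "wb", ])^2)))
  }

  te_centroid <- apply(wing[, lab, , drop = FALSE], c(1L, 3L), mean)
  vel <- te_centroid
  vel[1L, ] <- te_centroid[2L, ] - te_centroid[1L, ]
  vel[nfr, ] <- te_centroid[nfr, ] - te_centroid[nfr - 1L, ]
  if (nfr > 2L) {
    vel[2:(nfr - 1L), ] <- (te_centroid[3:nfr, ] - te_centroid[1:(nfr - 2L), ]) / 2
  }

  defl <- matrix(NA_real_, nfr, 4L, dimnames = list(NULL, lab))
  prev_normal <- NULL
  for (k in seq_len(nfr)) {
    motion <- vel[k, ]
    if (sqrt(sum(motion^2)) < freeze_speed * R && !is.null(prev_normal)) {
      motion <- prev_normal
    }
    pl <- fit_wing_plane(wing[k, "wb", ], wing[k, "mj", ], wing[k, "wt", ], motion)
    prev_normal <- pl$normal
    defl[k, ] <- te_deflection(pl, wing[k, lab, ], R)
  }

  out <- list(times = times, deflections = defl, wing_length_R = R)
  class(out) <- "deflection_series"
  out
}

#' Mid-stroke deflection values per trailing-edge landmark
#'
#' A half-stroke runs between two consecutive stroke reversals. Within each
#' half-stroke the mid-stroke instant is where the flapping angle crosses
#' the midpoint of the two bounding (sub-frame refined) reversal extremes;
#' the deflection of each landmark is linearly interpolated at that instant.
#' Half-strokes with decreasing flapping angle are labelled `down`, the
#' others `up`, and values are averaged over cycles per direction.
#'
#' @param kin a [wing_angles()] result.
#' @param defl a [deflection_series()] result on the same time base.
#' @return List with named vectors `midstroke_down` and `midstroke_up`
#'   (RP, MP, CuA, AA) and the per-half-stroke table `per_halfstroke`.
#' @export
midstroke_values <- function(kin, defl) {
  stopifnot(inherits(kin, "wing_kinematics"), inherits(defl, "deflection_series"))
  if (length(kin$reversal_times) < 2L) {
    stop("no complete half-stroke between reversals", call. = FALSE)
  }
  times <- kin$times
  phi <- kin$flapping_deg
  lab <- colnames(defl$deflections)
  rows <- list()
  for (i in seq_len(length(kin$reversal_times) - 1L)) {
    t0 <- kin$reversal_times[i]; t1 <- kin$reversal_times[i + 1L]
    mid <- (kin$reversal_values_deg[i] + kin$reversal_values_deg[i + 1L]) / 2
    direction <- if (kin$reversal_sense[i] > 0) "down" else "up"
    sel <- which(times >= t0 - 1e-12 & times <= t1 + 1e-12)
    if (length(sel) < 2L) next
    g <- phi[sel] - mid
    cross <- which(g[-length(g)] * g[-1L] <= 0 &
                     !(g[-length(g)] == 0 & g[-1L] == 0))
    if (!length(cross)) next
    k <- sel[cross[1L]]
    w <- if (g[cross[1L]] == g[cross[1L] + 1L]) 0 else
      g[cross[1L]] / (g[cross[1L]] - g[cross[1L] + 1L])
    t_mid <- times[k] + w * (times[k + 1L] - times[k])
    vals <- (1 - w) * defl$deflections[k, ] + w * defl$deflections[k + 1L, ]
    rows[[length(rows) + 1L]] <- data.frame(halfstroke = i, direction = direction,
                                            t_mid = t_mid, landmark = lab,
                                            deflection = as.numeric(vals))
  }
  if (!length(rows)) stop("no complete half-stroke between reversals", call. = FALSE)
  tab <- do.call(rbind, rows)
  avg <- function(dir) {
    sub <- tab[tab$direction == dir, ]
    if (!nrow(sub)) return(stats::setNames(rep(NA_real_, length(lab)), lab))
    stats::setNames(tapply(sub$deflection, factor(sub$landmark, levels = lab), mean), lab)
  }
  list(midstroke_down = avg("down"), midstroke_up = avg("up"), per_halfstroke = tab)
}

#' Span-wise profile of chord-wise trailing-edge deflection
#'
#' Monotone-preserving piecewise-cubic (Fritsch-Carlson) interpolation
#' through the per-landmark mid-stroke deflections as a function of
#' span-wise landmark position, used to visualize the span-wise gradient in
#' chord-wise deflection. The curve passes through the inputs exactly and
#' reproduces linear data exactly.
#'
#' @param deflections named values at the landmarks.
#' @param span_positions span-wise positions (fractions of wing length) of
#'   the same landmarks; must be distinct.
#' @param n number of curve samples.
#' @return Object of class `spanwise_profile`: the interpolant `fun` and a
#'   sampled `curve` data frame.
#' @export
spanwise_profile <- function(deflections, span_positions, n = 200L) {
  if (length(deflections) != length(span_positions) || length(deflections) < 2L) {
    stop("need matching deflections and span positions for at least 2 landmarks",
         call. = FALSE)
  }
  if (anyDuplicated(span_positions)) {
    stop("duplicated span positions", call. = FALSE)
  }
  ord <- order(span_positions)
  f <- stats::splinefun(span_positions[ord], deflections[ord], method = "monoH.FC")
  r <- seq(min(span_positions), max(span_positions), length.out = n)
  out <- list(fun = f,
              span = span_positions[ord], values = deflections[ord],
              curve = data.frame(span = r, deflection = f(r)))
  class(out) <- "spanwise_profile"
  out
}

#' Deflection-force allometry fit
#'
#' Ordinary least squares of `log(beta)` on `log(Fv)`, reported as the power
#' law `beta = a * Fv^b` with a t-based 95% confidence interval on the
#' exponent. `Fv` is the vertical force needed to sustain the observed
#' flight and `beta` a normalized trailing-edge deflection.
#'
#' @param Fv vector of vertical forces (N), all positive.
#' @param beta vector of deflections, all positive.
#' @return Object of class `allometric_fit` with fields `coefficient_a`,
#'   `exponent_b`, `ci95_b`, `r2`, `n` and the underlying `lm` fit.
#' @export
fit_allometry <- function(Fv, beta) {
  if (length(Fv) != length(beta) || length(Fv) < 3L) {
    stop("need at least 3 matched (Fv, beta) observations", call. = FALSE)
  }
  if (any(!is.finite(Fv)) || any(!is.finite(beta)) || any(Fv <= 0) || any(beta <= 0)) {
    stop("log transform undefined: Fv and beta must be positive", call. = FALSE)
  }
  fit <- stats::lm(log(beta) ~ log(Fv))
  cf <- stats::coef(fit)
  ci <- as.numeric(stats::confint(fit, "log(Fv)", level = 0.95))
  out <- list(coefficient_a = exp(unname(cf[1L])),
              exponent_b = unname(cf[2L]),
              ci95_b = ci,
              r2 = summary(fit)$r.squared,
              n = length(Fv),
              fit = fit)
  class(out) <- "allometric_fit"
  out
}

#' @export
print.allometric_fit <- function(x, ...) {
  cat(sprintf("beta = %.4g * Fv^%.3g   (95%% CI on exponent: %.3g - %.3g)\n",
              x$coefficient_a, x$exponent_b, x$ci95_b[1L], x$ci95_b[2L]))
  cat(sprintf("  n = %d, R^2 = %.3f\n", x$n, x$r2))
  invisible(x)
}

#' Chord-corrected flexural stiffness proxy
#'
#' Under the cantilever-beam assumption with equal bending force, the local
#' flexural stiffness is proportional to `l^3 / beta`, the cube of the local
#' chord length over the measured deflection. Comparing this proxy between
#' wings removes the direct geometric effect of longer chords.
#'
#' @param chord_l local chord length (m), positive.
#' @param beta measured deflection (m), positive.
#' @return `chord_l^3 / beta` (m^2), vectorized.
#' @export
stiffness_proxy <- function(chord_l, beta) {
  if (any(chord_l <= 0)) stop("'chord_l' must be positive", call. = FALSE)
  if (any(beta == 0)) stop("undeflected -- proxy undefined", call. = FALSE)
  if (any(beta < 0)) stop("'beta' must be positive", call. = FALSE)
  chord_l^3 / beta
}
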