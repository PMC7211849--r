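#' Body reference frame from three thorax points
#'
#' Builds a deterministic right-handed orthonormal triad from three
#' non-collinear points marked on the thorax: the longitudinal axis points
#' from the first to the second point, the dorsoventral axis is the normal
#' of the thorax triangle, and the lateral axis completes the triad. For the
#' canonical triad `(0,0,0), (1,0,0), (0,1,0)` the axes are the world axes.
#'
#' @param thorax 3 x 3 matrix, one point per row (mm).
#' @param tol minimum triangle area (relative to squared edge length) below
#'   which the triad is rejected as degenerate.
#' @return List with `origin` (first point) and `axes`, a 3 x 3 matrix whose
#'   columns are the longitudinal, lateral and dorsoventral unit axes.
#' @export
body_frame <- function(thorax, tol = 1e-8) {
  thorax <- as.matrix(thorax)
  stopifnot(nrow(thorax) == 3L, ncol(thorax) == 3L)
  e1 <- thorax[2L, ] - thorax[1L, ]
  v2 <- thorax[3L, ] - thorax[1L, ]
  nrm <- cross3(e1, v2)
  scale2 <- max(sum(e1^2), sum(v2^2))
  if (scale2 == 0 || vnorm(nrm) < tol * scale2) {
    stop("degenerate thorax triad: points are collinear or coincident", call. = FALSE)
  }
  ax1 <- unitize(e1)
  ax3 <- unitize(nrm)
  ax2 <- cross3(ax3, ax1)
  list(origin = thorax[1L, ], axes = cbind(ax1, ax2, ax3, deparse.level = 0))
}

# Express world points (n x 3) in a body frame.
to_body_coords <- function(xyz, frame) {
  sweep(as.matrix(xyz), 2L, frame$origin, `-`) %*% frame$axes
}

# Total-least-squares plane through a point cloud: returns unit normal
# (smallest principal axis) and centroid.
tls_plane <- function(xyz) {
  xyz <- as.matrix(xyz)
  ctr <- colMeans(xyz)
  sv <- svd(sweep(xyz, 2L, ctr, `-`))
  list(normal = sv$v[, 3L], centroid = ctr)
}

# Stroke reversals of an angle series: alternating extrema committed with a
# prominence hysteresis (an extremum counts only once the series has moved
# away from it by `prominence` times the series range, so measurement noise
# cannot create spurious reversals), then refined to sub-frame resolution
# with a parabola through the three samples around each extremum. Returns
# times, refined values and sense (+1 maximum, -1 minimum); boundary
# extrema (first/last sample) are dropped since they cannot be refined.
detect_reversals <- function(times, x, prominence = 0.2) {
  n <- length(x)
  if (n < 3L) stop("no reversals: series too short", call. = FALSE)
  thr <- prominence * diff(range(x))
  if (thr == 0) stop("no reversals in angle series", call. = FALSE)
  idx <- integer(0); sense <- integer(0)
  dir <- 0L  # 0 unknown, +1 rising, -1 falling
  cmax <- cmin <- 1L
  for (k in 2:n) {
    if (x[k] > x[cmax]) cmax <- k
    if (x[k] < x[cmin]) cmin <- k
    if (dir == 0L) {
      if (x[k] < x[cmax] - thr) {
        idx <- c(idx, cmax); sense <- c(sense, 1L); dir <- -1L; cmin <- k
      } else if (x[k] > x[cmin] + thr) {
        idx <- c(idx, cmin); sense <- c(sense, -1L); dir <- 1L; cmax <- k
      }
    } else if (dir < 0L && x[k] > x[cmin] + thr) {
      idx <- c(idx, cmin); sense <- c(sense, -1L); dir <- 1L; cmax <- k
    } else if (dir > 0L && x[k] < x[cmax] - thr) {
      idx <- c(idx, cmax); sense <- c(sense, 1L); dir <- -1L; cmin <- k
    }
  }
  # a half-stroke still in progress at the end leaves its extreme pending;
  # keep it only if the parabola check below confirms a genuine vertex
  if (dir > 0L) { idx <- c(idx, cmax); sense <- c(sense, 1L) }
  if (dir < 0L) { idx <- c(idx, cmin); sense <- c(sense, -1L) }
  if (length(idx) == 0L) stop("no reversals in angle series", call. = FALSE)
  dt <- times[2L] - times[1L]
  t_rev <- val <- numeric(length(idx))
  ok <- rep(TRUE, length(idx))
  for (i in seq_along(idx)) {
    km <- min(max(idx[i], 2L), n - 1L)  # shift the window inward at the ends
    y0 <- x[km - 1L]; y1 <- x[km]; y2 <- x[km + 1L]
    denom <- y0 - 2 * y1 + y2
    scale <- max(abs(c(y0, y1, y2)), 1)
    if (abs(denom) < 1e-12 * scale) {
      # no curvature: a flat plateau is a legitimate extremum, a straight
      # ramp (truncated half-stroke at a recording boundary) is not
      if (abs(y0 - y2) < 1e-12 * scale) off <- 0 else { ok[i] <- FALSE; next }
    } else {
      off <- 0.5 * (y0 - y2) / denom
    }
    # reject when the fitted vertex falls well outside the window; the 1.25
    # slack admits an extremum sitting on the boundary sample itself, where
    # the parabola fit of a sinusoid lands just past 1
    if (!is.finite(off) || abs(off) > 1.25) { ok[i] <- FALSE; next }
    off <- min(1, max(-1, off))
    t_rev[i] <- times[km] + off * dt
    val[i] <- if (idx[i] != km) x[idx[i]] else y1 - 0.25 * (y0 - y2) * off
  }
  if (!any(ok)) stop("no reversals in angle series", call. = FALSE)
  list(times = t_rev[ok], values = val[ok], sense = sense[ok],
       boundary = (idx == 1L | idx == n)[ok])
}

#' Reconstruct wing angles from a flight recording
#'
#' Expresses the wing landmarks in the per-frame body frame (from the thorax
#' triad) and inverts the rigid leading-edge geometry into the three
#' instantaneous angles: flapping (azimuth of the wb-wt span axis within the
#' stroke plane), deviation (elevation of the span axis out of the stroke
#' plane) and incidence (rotation of the leading-edge plane about the span
#' axis, against the stroke plane). If no stroke-plane angle is supplied it
#' is estimated as the total-least-squares plane of the wing-tip path in
#' body coordinates. Wingbeat reversals are detected on the flapping series
#' with parabolic sub-frame refinement and give the wingbeat frequency.
#'
#' @param recording a `flight_recording` (or compatible list with `times`
#'   and labelled `points`).
#' @param stroke_plane_deg known stroke-plane inclination (deg) or `NULL` to
#'   estimate it from the tip path.
#' @param smooth_window optional odd moving-average window (frames) applied
#'   to the landmark trajectories before inversion; `NULL` (default) leaves
#'   the data untouched.
#' @return Object of class `wing_kinematics`: time series of the three
#'   angles (deg), the stroke-plane angle used, reversal times/senses, the
#'   wingbeat frequency (Hz), the tip path in body coordinates, the
#'   estimated wing length and indices of frames with a degenerate
#'   leading-edge triangle.
#' @export
wing_angles <- function(recording, stroke_plane_deg = NULL, smooth_window = NULL) {
  pts <- recording$points
  times <- recording$times
  need <- c("th1", "th2", "th3", "wb", "mj", "wt")
  missing_lab <- setdiff(need, dimnames(pts)[[2L]])
  if (length(missing_lab)) {
    stop("missing landmark(s): ", paste(missing_lab, collapse = ", "), call. = FALSE)
  }
  nfr <- dim(pts)[1L]
  if (!is.null(smooth_window) && smooth_window > 1L) {
    w <- as.integer(smooth_window)
    if (w %% 2L == 0L) stop("'smooth_window' must be odd", call. = FALSE)
    kern <- rep(1 / w, w)
    for (j in seq_len(dim(pts)[2L])) for (d in 1:3) {
      sm <- as.numeric(stats::filter(pts[, j, d], kern, sides = 2L))
      keep <- is.na(sm)  # window does not fit at the ends; leave those frames raw
      sm[keep] <- pts[, j, d][keep]
      pts[, j, d] <- sm
    }
  }

  wb <- mj <- wt <- matrix(NA_real_, nfr, 3L)
  for (k in seq_len(nfr)) {
    fr <- body_frame(pts[k, c("th1", "th2", "th3"), ])
    wing <- to_body_coords(pts[k, c("wb", "mj", "wt"), ], fr)
    wb[k, ] <- wing[1L, ]; mj[k, ] <- wing[2L, ]; wt[k, ] <- wing[3L, ]
  }
  tip <- wt - wb
  R_mm <- mean(sqrt(rowSums(tip^2)))

  if (is.null(stroke_plane_deg)) {
    normal <- tls_plane(tip)$normal
    if (normal[3L] < 0) normal <- -normal
    stroke_plane_deg <- acos(min(1, max(-1, normal[3L]))) * RAD2DEG
  }
  basis <- stroke_basis(stroke_plane_deg * DEG2RAD)

  flapping <- deviation <- incidence <- numeric(nfr)
  flagged <- integer(0)
  for (k in seq_len(nfr)) {
    u <- unitize(tip[k, ])
    deviation[k] <- asin(min(1, max(-1, sum(u * basis$n))))
    flapping[k] <- atan2(sum(u * basis$u1), sum(u * basis$u2))
    le1 <- mj[k, ] - wb[k, ]
    nr <- cross3(le1, tip[k, ])
    if (vnorm(nr) < 1e-8 * R_mm^2) {
      flagged <- c(flagged, k)
      incidence[k] <- NA_real_
      next
    }
    nhat <- unitize(nr)
    cf <- chord_frame(u, basis)
    incidence[k] <- atan2(-sum(nhat * cf$p), sum(nhat * cf$q))
  }

  rev <- detect_reversals(times, flapping)
  freq <- reversal_frequency(rev)

  out <- list(times = times,
              flapping_deg = flapping * RAD2DEG,
              deviation_deg = deviation * RAD2DEG,
              incidence_deg = incidence * RAD2DEG,
              stroke_plane_deg = stroke_plane_deg,
              reversal_times = rev$times,
              reversal_values_deg = rev$values * RAD2DEG,
              reversal_sense = rev$sense,
              reversal_boundary = rev$boundary,
              frequency_hz = freq,
              tip_body = tip,
              wing_length_mm = R_mm,
              flagged_frames = flagged)
  class(out) <- "wing_kinematics"
  out
}

reversal_frequency <- function(rev) {
  if (is.null(rev$boundary)) rev$boundary <- rep(FALSE, length(rev$times))
  # interior reversals are refined on a full parabola window; extrema lying
  # on the first/last frame are clamped and slightly biased, so use them
  # only when too few interior reversals exist
  for (interior_only in c(TRUE, FALSE)) {
    for (s in c(1, -1)) {
      pick <- rev$sense == s & (!interior_only | !rev$boundary)
      t_s <- rev$times[pick]
      if (length(t_s) >= 2L) {
        return((length(t_s) - 1L) / (t_s[length(t_s)] - t_s[1L]))
      }
    }
  }
  stop("no reversals: need at least two same-sense stroke reversals", call. = FALSE)
}

#' Wingbeat frequency from detected stroke reversals
#'
#' Number of full cycles divided by the elapsed time between the first and
#' last same-sense reversal of the flapping angle.
#'
#' @param kin a [wing_angles()] result.
#' @return Frequency in Hz.
#' @export
wingbeat_frequency <- function(kin) {
  stopifnot(inherits(kin, "wing_kinematics"))
  reversal_frequency(list(times = kin$reversal_times, sense = kin$reversal_sense,
                          boundary = kin$reversal_boundary))
}

#' Stroke-plane angle from the wing-tip path
#'
#' Fits a total-least-squares plane to the body-frame wing-tip path of each
#' full wingbeat cycle (between consecutive same-sense reversals), takes the
#' angle between that plane and the body horizontal, and averages over
#' cycles. The result lies in `[0, 90]` degrees.
#'
#' @param kin a [wing_angles()] result.
#' @param tip optional frames x 3 matrix of tip positions in body
#'   coordinates; defaults to the tip path stored in `kin`.
#' @return Mean stroke-plane angle, deg.
#' @export
stroke_plane <- function(kin, tip = kin$tip_body) {
  stopifnot(inherits(kin, "wing_kinematics"))
  s <- kin$reversal_sense[1L]
  bounds <- kin$reversal_times[kin$reversal_sense == s]
  if (length(bounds) < 2L) stop("need at least one full wingbeat cycle", call. = FALSE)
  angles <- numeric(length(bounds) - 1L)
  for (i in seq_along(angles)) {
    sel <- kin$times >= bounds[i] & kin$times <= bounds[i + 1L]
    nrm <- tls_plane(tip[sel, , drop = FALSE])$normal
    angles[i] <- acos(min(1, abs(nrm[3L]))) * RAD2DEG
  }
  mean(angles)
}

#' Advance ratio of flapping flight
#'
#' Ratio of flight speed to mean wing-tip flapping speed,
#' `J = V / (2 * Phi * f * R)`. Values well below 0.1 indicate a
#' hovering-like regime.
#'
#' @param flight_speed flight speed, m/s.
#' @param Phi peak-to-peak flapping amplitude, rad.
#' @param f wingbeat frequency, Hz.
#' @param R wing length, m.
#' @return Dimensionless advance ratio.
#' @export
advance_ratio <- function(flight_speed, Phi, f, R) {
  stopifnot_scalar_pos(Phi, "Phi")
  stopifnot_scalar_pos(f, "f")
  stopifnot_scalar_pos(R, "R")
  if (flight_speed < 0) stop("'flight_speed' must be >= 0", call. = FALSE)
  flight_speed / (2 * Phi * f * R)
}

#' Vertical force required to sustain the observed flight
#'
#' `Fv = m * (g + a_v)` with `g = 9.81` m/s^2. A negative vertical
#' acceleration reduces the requirement; the value is returned as computed.
#'
#' @param mass_kg body mass, kg.
#' @param vertical_acceleration m/s^2.
#' @return Vertical force, N.
#' @export
vertical_force <- function(mass_kg, vertical_acceleration = 0) {
  stopifnot_scalar_pos(mass_kg, "mass_kg")
  mass_kg * (9.81 + vertical_acceleration)
}

#' @export
print.wing_kinematics <- function(x, ...) {
  cat(sprintf("<wing_kinematics> %d frames; wingbeat %.2f Hz; stroke plane %.1f deg\n",
              length(x$times), x$frequency_hz, x$stroke_plane_deg))
  cat(sprintf("  flapping range [%.1f, %.1f] deg; %d reversal(s); %d flagged frame(s)\n",
              min(x$flapping_deg), max(x$flapping_deg),
              length(x$reversal_times), length(x$flagged_frames)))
  invisible(x)
}

#' @export
plot.wing_kinematics <- function(x, ...) {
  graphics::matplot(x$times * 1000,
                    cbind(x$flapping_deg, x$deviation_deg, x$incidence_deg),
                    type = "l", lty = 1, col = c("darkgreen", "red", "blue"),
                    xlab = "time (ms)", ylab = "angle (deg)", ...)
  graphics::legend("topright", c("flapping", "deviation", "incidence"),
                   col = c("darkgreen", "red", "blue"), lty = 1, bty = "n")
  invisible(x)
}
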