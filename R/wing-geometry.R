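#' Wing outline polygon
#'
#' @param vertices ordered m x 2 matrix of outline vertices (mm); the
#'   polygon is closed implicitly and must be simple (non-self-intersecting)
#'   with positive area.
#' @param span_axis unit 2-vector from wing base toward the tip (defaults to
#'   the x axis).
#' @return Object of class `wing_outline`.
#' @export
wing_outline <- function(vertices, span_axis = c(1, 0)) {
  v <- as.matrix(vertices)
  stopifnot(ncol(v) == 2L, nrow(v) >= 3L)
  if (nrow(v) > 3L && vnorm(v[1L, ] - v[nrow(v), ]) < 1e-12) v <- v[-nrow(v), ]
  if (polygon_self_intersects(v)) {
    stop("self-intersecting outline polygon", call. = FALSE)
  }
  if (abs(shoelace_area(v)) <= 0) stop("outline has zero area", call. = FALSE)
  span_axis <- span_axis / sqrt(sum(span_axis^2))
  out <- list(polygon = v, span_axis = as.numeric(span_axis))
  class(out) <- "wing_outline"
  out
}

shoelace_area <- function(v) {
  x <- v[, 1L]; y <- v[, 2L]
  xn <- c(x[-1L], x[1L]); yn <- c(y[-1L], y[1L])
  sum(x * yn - xn * y) / 2
}

segments_intersect <- function(p1, p2, p3, p4) {
  d <- function(a, b, c) (b[1L] - a[1L]) * (c[2L] - a[2L]) - (b[2L] - a[2L]) * (c[1L] - a[1L])
  d1 <- d(p3, p4, p1); d2 <- d(p3, p4, p2); d3 <- d(p1, p2, p3); d4 <- d(p1, p2, p4)
  (d1 * d2 < 0) && (d3 * d4 < 0)
}

polygon_self_intersects <- function(v) {
  m <- nrow(v)
  idx <- cbind(seq_len(m), c(seq_len(m)[-1L], 1L))
  for (i in seq_len(m - 2L)) {
    for (j in (i + 2L):m) {
      if (i == 1L && j == m) next  # adjacent through closure
      if (segments_intersect(v[idx[i, 1L], ], v[idx[i, 2L], ],
                             v[idx[j, 1L], ], v[idx[j, 2L], ])) return(TRUE)
    }
  }
  FALSE
}

# Rotate outline coordinates into (span, chord) axes, span from the base.
span_coords <- function(outline) {
  e1 <- outline$span_axis
  e2 <- c(-e1[2L], e1[1L])
  u <- outline$polygon %*% cbind(e1, e2)
  u[, 1L] <- u[, 1L] - min(u[, 1L])
  u
}

#' Chord distribution along the span
#'
#' Chord at span station `r` is the total length of the intersection of the
#' outline with the line perpendicular to the span axis at `r` (measured
#' from the wing base, the proximal end of the outline's span extent).
#' Stations are strip midpoints, so vertices never coincide with a cut.
#'
#' @param outline a [wing_outline()].
#' @param n number of span-wise stations.
#' @return `data.frame` with columns `r` (mm from the base) and `chord`
#'   (mm, non-negative).
#' @export
chord_distribution <- function(outline, n = 500L) {
  stopifnot(inherits(outline, "wing_outline"))
  u <- span_coords(outline)
  b <- max(u[, 1L])
  dr <- b / n
  r <- (seq_len(n) - 0.5) * dr
  m <- nrow(u)
  nxt <- c(seq_len(m)[-1L], 1L)
  chord <- numeric(n)
  for (i in seq_len(n)) {
    x <- r[i]
    if (any(abs(u[, 1L] - x) < 1e-12 * max(b, 1))) x <- x + 1e-9 * dr
    cr <- (u[, 1L] - x) * (u[nxt, 1L] - x) < 0
    if (!any(cr)) next
    tfrac <- (x - u[cr, 1L]) / (u[nxt, 1L][cr] - u[cr, 1L])
    ys <- sort(u[cr, 2L] + tfrac * (u[nxt, 2L][cr] - u[cr, 2L]))
    chord[i] <- sum(ys[seq(2L, length(ys), by = 2L)] -
                      ys[seq(1L, length(ys), by = 2L)])
  }
  data.frame(r = r, chord = chord)
}

#' Planform metrics: span, area, aspect ratio
#'
#' Span is the outline's extent along the span axis, area the shoelace
#' polygon area, and aspect ratio `AR = b^2 / S`.
#'
#' @param outline a [wing_outline()].
#' @return List of class `wing_geometry` with `span_b` (mm), `area_S`
#'   (mm^2), `aspect_ratio_AR`.
#' @export
planform_metrics <- function(outline) {
  stopifnot(inherits(outline, "wing_outline"))
  u <- span_coords(outline)
  b <- max(u[, 1L])
  S <- abs(shoelace_area(outline$polygon))
  out <- list(span_b = b, area_S = S, aspect_ratio_AR = b^2 / S)
  class(out) <- "wing_geometry"
  out
}

#' Non-dimensional radius of the second moment of wing area
#'
#' Strip integration of the chord distribution measured from the wing base:
#' `S2 = sum c(r_i) r_i^2 dr` (midpoint rule) and
#' `r2_hat = sqrt(S2 / (S * b^2))`, with `S` the polygon area and `b` the
#' span. A rectangular planform gives `1/sqrt(3)`, a linearly tapering one
#' `1/sqrt(6)`; larger values mean area concentrated toward the tip.
#'
#' @param outline a [wing_outline()].
#' @param n_strips number of span-wise strips (>= 10).
#' @return List with `S2` (mm^4), `r2_hat` (dimensionless, in (0, 1)).
#' @export
second_moment <- function(outline, n_strips = 500L) {
  if (n_strips < 10L) stop("'n_strips' must be >= 10", call. = FALSE)
  cd <- chord_distribution(outline, n = n_strips)
  if (all(cd$chord <= 0)) stop("zero chord everywhere", call. = FALSE)
  g <- planform_metrics(outline)
  dr <- cd$r[2L] - cd$r[1L]
  S2 <- sum(cd$chord * cd$r^2) * dr
  list(S2 = S2, r2_hat = sqrt(S2 / (g$area_S * g$span_b^2)))
}

#' @export
print.wing_geometry <- function(x, ...) {
  cat(sprintf("<wing_geometry> span %.2f mm, area %.2f mm^2, AR %.2f\n",
              x$span_b, x$area_S, x$aspect_ratio_AR))
  invisible(x)
}

#' Synthetic wing planforms
#'
#' Deterministic outline polygons for testing and comparison: `rectangular`
#' and `triangular` planforms with closed-form second moments, a `circular`
#' 64-gon, and two beetle-like shapes built from smooth chord laws --
#' `distal_loaded` (high aspect ratio, area shifted toward the tip) and
#' `proximal_loaded` (low aspect ratio, broad base).
#'
#' @param type planform type.
#' @param span span (mm).
#' @param chord reference chord (mm); for `circular`, the diameter equals
#'   `span`.
#' @param n vertices per edge for the smooth planforms.
#' @return A [wing_outline()].
#' @export
synthetic_planform <- function(type = c("rectangular", "triangular", "circular",
                                        "distal_loaded", "proximal_loaded"),
                               span = 20, chord = 5, n = 64L) {
  type <- match.arg(type)
  v <- switch(type,
    rectangular = rbind(c(0, 0), c(span, 0), c(span, chord), c(0, chord)),
    triangular = rbind(c(0, 0), c(span, 0), c(0, chord)),
    circular = {
      th <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
      cbind(span / 2 * cos(th) + span / 2, span / 2 * sin(th))
    },
    distal_loaded = chordlaw_polygon(span, chord * 0.7,
                                     function(t) sqrt(pmax(t, 0)) * (1 - t^8), n),
    proximal_loaded = chordlaw_polygon(span * 0.8, chord * 1.4,
                                       function(t) (1 - t) * (1 - (1 - t)^8) + 1e-3, n))
  wing_outline(v)
}

chordlaw_polygon <- function(span, c0, law, n) {
  t <- seq(1e-3, 1 - 1e-3, length.out = n)
  upper <- cbind(t * span, c0 * law(t) / 2)
  lower <- cbind(rev(t) * span, -c0 * law(rev(t)) / 2)
  rbind(upper, lower)
}
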