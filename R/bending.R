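#' Simulate a point-load cantilever bending measurement
#'
#' Forward model of the static bending protocol: a wing clamped as a
#' cantilever is pressed down by a fixed displacement `beta` at distance `l`
#' from the support, and the restoring force is recorded. For a uniform
#' beam `F = k * EI * beta / l^3`; multiplicative log-normal noise with
#' coefficient of variation `noise_cv` emulates transducer scatter.
#' `noise_cv = 0` returns the exact closed-form force.
#'
#' @param EI flexural stiffness, N m^2 (scalar or vector).
#' @param l distance from support to load point, m.
#' @param k dimensionless beam constant (3 for an end-loaded uniform
#'   cantilever).
#' @param displacement imposed deflection `beta`, m (the protocol uses 1 mm).
#' @param noise_cv coefficient of variation of multiplicative noise.
#' @param seed RNG seed (private stream).
#' @param point_id,side,support optional metadata columns recycled across
#'   measurements: measurement location 1-6, `"dorsal"`/`"ventral"` loading
#'   side, `"WB"` (wing-base clamp) or `"WBLE"` (base plus leading-edge
#'   support).
#' @param force_floor forces below this value (N) are flagged (not dropped)
#'   in the `flagged` column.
#' @return A `data.frame` of class `bending_record` with columns `point_id`,
#'   `side`, `support`, `force_F`, `displacement_beta`, `distance_l`,
#'   `flagged`.
#' @export
simulate_bending <- function(EI, l, k = 3, displacement = 1e-3, noise_cv = 0,
                             seed = 1L, point_id = 1L, side = "dorsal",
                             support = "WB", force_floor = 1e-6) {
  if (any(EI <= 0)) stop("'EI' must be positive", call. = FALSE)
  if (any(l <= 0)) stop("'l' must be positive", call. = FALSE)
  if (any(displacement <= 0)) stop("'displacement' must be positive", call. = FALSE)
  stopifnot_scalar_pos(k, "k")
  if (noise_cv < 0) stop("'noise_cv' must be >= 0", call. = FALSE)
  n <- max(length(EI), length(l), length(displacement), length(point_id),
           length(side), length(support))
  EI <- rep_len(EI, n); l <- rep_len(l, n); displacement <- rep_len(displacement, n)
  F <- k * EI * displacement / l^3
  if (noise_cv > 0) {
    F <- F * with_private_seed(seed, exp(stats::rnorm(n, 0, noise_cv)))
  }
  out <- data.frame(point_id = rep_len(point_id, n),
                    side = normalize_side(rep_len(side, n)),
                    support = rep_len(support, n),
                    force_F = F,
                    displacement_beta = displacement,
                    distance_l = l,
                    flagged = F < force_floor)
  class(out) <- c("bending_record", "data.frame")
  out
}

normalize_side <- function(side) {
  if (is.numeric(side)) side <- c("dorsal", "ventral")[side]
  side <- tolower(as.character(side))
  if (!all(side %in% c("dorsal", "ventral"))) {
    stop("'side' must be dorsal (1) or ventral (2)", call. = FALSE)
  }
  side
}

#' Simulate a deflection-force allometry dataset
#'
#' Draws vertical forces `Fv` log-uniformly over a range and generates
#' deflections on the power law `beta = a * Fv^b` with log-normal scatter.
#' With zero noise the points lie exactly on the power law.
#'
#' @param a power-law coefficient (> 0).
#' @param b power-law exponent.
#' @param Fv_range length-2 positive range of vertical forces, N.
#' @param n number of observations (>= 3).
#' @param log_noise_sigma s.d. of Gaussian noise added to `log(beta)`.
#' @param seed RNG seed (private stream).
#' @return `data.frame` with columns `Fv` and `beta`.
#' @export
simulate_allometry <- function(a = 0.038, b = 0.43, Fv_range = c(2e-3, 1e-2),
                               n = 30L, log_noise_sigma = 0, seed = 1L) {
  stopifnot_scalar_pos(a, "a")
  if (any(Fv_range <= 0) || length(Fv_range) != 2L) {
    stop("'Fv_range' must be two positive values", call. = FALSE)
  }
  if (n < 3L) stop("'n' must be at least 3", call. = FALSE)
  with_private_seed(seed, {
    Fv <- exp(stats::runif(n, log(min(Fv_range)), log(max(Fv_range))))
    beta <- a * Fv^b
    if (log_noise_sigma > 0) beta <- beta * exp(stats::rnorm(n, 0, log_noise_sigma))
    data.frame(Fv = Fv, beta = beta)
  })
}

#' Flexural stiffness from a point-load bending measurement
#'
#' Inverts the uniform-cantilever relation `beta = F * l^3 / (k * EI)`:
#' `EI = F * l^3 / (k * beta)`. With `k = 3` (end-loaded uniform beam) this
#' is the standard estimate; real wings are non-uniform, so `k` is exposed.
#'
#' @param F measured force, N.
#' @param l distance from support to load point, m.
#' @param beta imposed deflection, m.
#' @param k dimensionless beam constant.
#' @return Flexural stiffness EI, N m^2 (vectorized).
#' @export
flexural_stiffness <- function(F, l, beta, k = 3) {
  if (any(F <= 0) || any(l <= 0) || any(beta <= 0) || any(k <= 0)) {
    stop("all of F, l, beta, k must be positive", call. = FALSE)
  }
  F * l^3 / (k * beta)
}

cell_means <- function(records, by) {
  stopifnot(is.data.frame(records))
  need <- c("point_id", "side", "support", "force_F")
  miss <- setdiff(need, names(records))
  if (length(miss)) stop("bending records lack column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  records$side <- normalize_side(records$side)
  stats::aggregate(force_F ~ point_id + side + support, data = records, FUN = mean)
}

contrast_table <- function(records, contrast_var, level_hi, level_lo, keep_vars) {
  m <- cell_means(records)
  wide <- stats::reshape(m, idvar = c("point_id", keep_vars),
                         timevar = contrast_var, direction = "wide")
  hi <- paste0("force_F.", level_hi); lo <- paste0("force_F.", level_lo)
  for (col in c(hi, lo)) if (is.null(wide[[col]])) wide[[col]] <- NA_real_
  bad <- is.na(wide[[hi]]) | is.na(wide[[lo]])
  if (any(bad)) {
    cells <- apply(wide[bad, c("point_id", keep_vars), drop = FALSE], 1L,
                   paste, collapse = "/")
    stop(sprintf("unmatched %s pair(s) at: %s", contrast_var,
                 paste(cells, collapse = ", ")), call. = FALSE)
  }
  out <- wide[c("point_id", keep_vars)]
  out$force_diff <- wide[[hi]] - wide[[lo]]
  out[order(out$point_id), , drop = FALSE]
}

#' Dorsal-ventral asymmetry of bending force
#'
#' Per-point signed difference of the mean force needed to bend the wing
#' from the dorsal side minus the ventral side, separately for each wing
#' support. Zero for a dorso-ventrally symmetric wing.
#'
#' @param records `data.frame` with columns `point_id`, `side`, `support`,
#'   `force_F` (e.g. from [simulate_bending()] or [read_bending_csv()]).
#' @return `data.frame` with `point_id`, `support`, `force_diff` (N).
#' @export
side_asymmetry <- function(records) {
  contrast_table(records, "side", "dorsal", "ventral", "support")
}

#' Effect of the leading-edge support on bending force
#'
#' Per-point signed difference of mean bending force with the wing secured
#' at base plus leading edge (WBLE) minus base only (WB), separately per
#' loading side. Positive values indicate the leading-edge support stiffens
#' the wing at that point (typically by suppressing wing twist).
#'
#' @inheritParams side_asymmetry
#' @return `data.frame` with `point_id`, `side`, `force_diff` (N).
#' @export
support_effect <- function(records) {
  contrast_table(records, "support", "WBLE", "WB", "side")
}

#' Two-sided permutation test for a difference in group means
#'
#' Randomly re-assigns observations to the two groups `n_perm` times and
#' compares the absolute observed mean difference with the permutation
#' distribution, with the add-one correction
#' `p = (1 + #{|perm diff| >= |obs|}) / (1 + n_perm)`.
#'
#' @param group_a,group_b numeric vectors, each of length >= 2.
#' @param n_perm number of random permutations; fewer than 100 triggers a
#'   warning.
#' @param seed RNG seed (private stream).
#' @return List with `observed_diff`, `p_value`, `n_perm`.
#' @export
permutation_contrast <- function(group_a, group_b, n_perm = 999L, seed = 1L) {
  if (length(group_a) < 2L || length(group_b) < 2L) {
    stop("each group needs at least 2 observations", call. = FALSE)
  }
  if (n_perm < 100L) warning("n_perm < 100: permutation p-value will be coarse")
  obs <- mean(group_a) - mean(group_b)
  pooled <- c(group_a, group_b)
  na <- length(group_a)
  exceed <- with_private_seed(seed, {
    cnt <- 0L
    for (i in seq_len(n_perm)) {
      idx <- sample.int(length(pooled), na)
      d <- mean(pooled[idx]) - mean(pooled[-idx])
      if (abs(d) >= abs(obs)) cnt <- cnt + 1L
    }
    cnt
  })
  list(observed_diff = obs,
       p_value = (1 + exceed) / (1 + n_perm),
       n_perm = as.integer(n_perm))
}
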