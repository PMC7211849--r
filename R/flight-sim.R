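#' Parameters for a synthetic flapping-flight recording
#'
#' Builds and validates the full parameter set of the forward model used by
#' [simulate_flight()]. The defaults describe a beetle-sized flyer in slow
#' forward flight: a 20 mm wing flapped at 118 Hz through a 120 deg
#' (peak-to-peak) stroke in a stroke plane inclined 34 deg from horizontal,
#' with the four trailing-edge landmarks (RP, MP, CuA, AA) deflecting
#' elastically out of the rigid leading-edge plane, CuA the most compliant.
#'
#' @param wing_length_R wing length from base (wb) to tip (wt), mm.
#' @param frequency_f wingbeat frequency, Hz.
#' @param stroke_amplitude_Phi peak-to-peak flapping amplitude, deg.
#' @param stroke_plane_angle stroke-plane inclination from horizontal, deg.
#' @param deviation_amplitude amplitude of the figure-of-eight deviation
#'   (elevation out of the stroke plane), deg.
#' @param incidence_profile function mapping cycle phase in `[0, 1)` to the
#'   incidence angle (deg) of the wing plane about the span axis, measured
#'   against the stroke plane. The default `45 * sin(2*pi*phase)` pitches the
#'   wing symmetrically in the two half-strokes and vanishes at reversals.
#' @param te_deflection_amplitudes named vector (RP, MP, CuA, AA) of peak
#'   out-of-plane trailing-edge deflections, as fractions of `wing_length_R`;
#'   each must lie in `[0, 0.5]`.
#' @param te_chord_positions 4 x 2 matrix (rows RP, MP, CuA, AA) of span-wise
#'   and chord-wise landmark positions on the wing plane, as fractions of
#'   `wing_length_R`. Chord is positive rearward (toward the trailing edge).
#' @param mj_position length-2 (span, chord) position of the marginal-joint
#'   landmark on the leading edge; it must be off the wb-wt axis so the three
#'   leading-edge landmarks define a plane.
#' @param body_velocity 3-vector, m/s, in world axes (x forward, z up).
#' @param body_vertical_acceleration m/s^2.
#' @param body_mass_g body mass, g.
#' @param n_cycles number of full wingbeat cycles to generate (>= 1).
#' @param frame_rate sampling rate, Hz; defaults to `40 * frequency_f` so
#'   that frames fall exactly on stroke reversals and mid-strokes. Must be at
#'   least 20 samples per cycle.
#' @param noise_sigma s.d. of isotropic Gaussian digitization noise added to
#'   every coordinate, mm.
#' @param seed integer seed for the generator's private RNG stream.
#' @return An object of class `flight_sim_params` (a validated list).
#' @seealso [simulate_flight()]
#' @export
flight_sim_params <- function(wing_length_R = 20,
                              frequency_f = 118,
                              stroke_amplitude_Phi = 120,
                              stroke_plane_angle = 34,
                              deviation_amplitude = 5,
                              incidence_profile = function(phase) 45 * sin(2 * pi * phase),
                              te_deflection_amplitudes = c(RP = 0.04, MP = 0.07,
                                                           CuA = 0.12, AA = 0.08),
                              te_chord_positions = default_te_positions(),
                              mj_position = c(span = 0.55, chord = -0.22),
                              body_velocity = c(0, 0, 0),
                              body_vertical_acceleration = 0,
                              body_mass_g = 0.5,
                              n_cycles = 3,
                              frame_rate = NULL,
                              noise_sigma = 0,
                              seed = 1L) {
  stopifnot_scalar_pos(wing_length_R, "wing_length_R")
  stopifnot_scalar_pos(frequency_f, "frequency_f")
  stopifnot_scalar_pos(stroke_amplitude_Phi, "stroke_amplitude_Phi")
  if (is.null(frame_rate)) frame_rate <- 40 * frequency_f
  if (frame_rate < 20 * frequency_f) {
    stop("undersampled: frame_rate must be at least 20 samples per wingbeat cycle",
         call. = FALSE)
  }
  if (deviation_amplitude < 0) stop("'deviation_amplitude' must be >= 0", call. = FALSE)
  if (!is.function(incidence_profile)) stop("'incidence_profile' must be a function", call. = FALSE)
  lm_names <- c("RP", "MP", "CuA", "AA")
  if (!all(lm_names %in% names(te_deflection_amplitudes))) {
    stop("'te_deflection_amplitudes' must be named RP, MP, CuA, AA", call. = FALSE)
  }
  te_deflection_amplitudes <- te_deflection_amplitudes[lm_names]
  if (any(te_deflection_amplitudes < 0 | te_deflection_amplitudes > 0.5)) {
    stop("trailing-edge deflection amplitudes must lie in [0, 0.5] of wing length",
         call. = FALSE)
  }
  te_chord_positions <- as.matrix(te_chord_positions)
  if (!all(lm_names %in% rownames(te_chord_positions)) || ncol(te_chord_positions) != 2L) {
    stop("'te_chord_positions' must be a 4 x 2 matrix with rows RP, MP, CuA, AA",
         call. = FALSE)
  }
  te_chord_positions <- te_chord_positions[lm_names, , drop = FALSE]
  if (length(mj_position) != 2L || mj_position[2L] == 0) {
    stop("'mj_position' must be (span, chord) with a nonzero chord offset",
         call. = FALSE)
  }
  if (n_cycles < 1) stop("'n_cycles' must be >= 1", call. = FALSE)
  if (noise_sigma < 0) stop("'noise_sigma' must be >= 0", call. = FALSE)
  stopifnot_scalar_pos(body_mass_g, "body_mass_g")
  out <- list(wing_length_R = wing_length_R, frequency_f = frequency_f,
              stroke_amplitude_Phi = stroke_amplitude_Phi,
              stroke_plane_angle = stroke_plane_angle,
              deviation_amplitude = deviation_amplitude,
              incidence_profile = incidence_profile,
              te_deflection_amplitudes = te_deflection_amplitudes,
              te_chord_positions = te_chord_positions,
              mj_position = as.numeric(mj_position),
              body_velocity = as.numeric(body_velocity),
              body_vertical_acceleration = body_vertical_acceleration,
              body_mass_g = body_mass_g,
              n_cycles = n_cycles, frame_rate = frame_rate,
              noise_sigma = noise_sigma, seed = seed)
  class(out) <- "flight_sim_params"
  out
}

#' Default trailing-edge landmark layout
#'
#' Span-wise/chord-wise positions (fractions of wing length) of the four
#' trailing-edge vein tips on the wing plane, RP most distal and AA most
#' proximal, approximating a scarab hind-wing planform with the base-to-tip
#' axis as the span reference.
#' @return 4 x 2 matrix with rows RP, MP, CuA, AA and columns span, chord.
#' @export
default_te_positions <- function() {
  m <- rbind(RP = c(0.80, 0.14), MP = c(0.62, 0.22),
             CuA = c(0.42, 0.28), AA = c(0.22, 0.25))
  colnames(m) <- c("span", "chord")
  m
}

# Orthonormal stroke-plane basis in body axes for inclination gamma (rad).
# u2 = lateral (flapping reference), u1 = fore-aft in-plane axis, n = normal.
stroke_basis <- function(gamma) {
  list(u1 = c(cos(gamma), 0, -sin(gamma)),
       u2 = c(0, 1, 0),
       n  = c(sin(gamma), 0, cos(gamma)))
}

# Recover the canonical stroke basis from an arbitrary unit plane normal:
# the lateral axis is the intersection of the stroke plane with the body
# sagittal-normal direction. Matches stroke_basis() when the plane is tilted
# about the lateral axis.
stroke_basis_from_normal <- function(n) {
  n <- unitize(if (n[3L] < 0) -n else n)
  u2 <- unitize(cross3(n, c(1, 0, 0)))
  list(u1 = cross3(u2, n), u2 = u2, n = n)
}

# Span unit vector for flapping phi and deviation theta (rad) in a basis.
span_vector <- function(phi, theta, basis) {
  cos(theta) * (cos(phi) * basis$u2 + sin(phi) * basis$u1) + sin(theta) * basis$n
}

# In-plane direction perpendicular to the span axis (p) and the companion
# out-of-plane direction (q = s x p). The wing chord at incidence alpha is
# cos(alpha) * p + sin(alpha) * q; the wing-plane normal is s x chord.
chord_frame <- function(s, basis) {
  p <- unitize(cross3(basis$n, s))
  list(p = p, q = cross3(s, p))
}

wing_point_labels <- function() {
  c("th1", "th2", "th3", "wb", "mj", "wt", "RP", "MP", "CuA", "AA")
}

#' Simulate a free-flight recording of a flapping, elastically deforming wing
#'
#' Forward model of a 3D videography measurement: three thorax points move as
#' a rigid triad translated by the body velocity; three leading-edge
#' landmarks (wb, mj, wt) move rigidly with the commanded flapping, deviation
#' and incidence angles; the four trailing-edge landmarks (RP, MP, CuA, AA)
#' are additionally displaced perpendicular to the leading-edge plane by
#' `amplitude * |sin(stroke phase)|` of the wing length -- peaking at
#' mid-stroke, vanishing at stroke reversals, and signed toward the
#' instantaneous direction of wing motion (the pressure side). Isotropic
#' Gaussian noise is added last. The same seed gives bit-identical output.
#'
#' @param params a [flight_sim_params()] object.
#' @return An object of class `flight_recording`: a list with `times` (s),
#'   `points` (frames x 10 labelled points x 3 world coordinates, mm), and
#'   `ground_truth` (the generating angle series in deg, the normalized
#'   deflection series, and the commanded stroke-plane angle and frequency).
#' @examples
#' rec <- simulate_flight(flight_sim_params(noise_sigma = 0, n_cycles = 2))
#' rec
#' @export
simulate_flight <- function(params) {
  stopifnot(inherits(params, "flight_sim_params"))
  p <- params
  R <- p$wing_length_R
  f <- p$frequency_f
  K <- round(p$n_cycles * p$frame_rate / f)
  times <- (0:K) / p$frame_rate
  nfr <- length(times)
  phase <- f * times
  wtph <- 2 * pi * phase

  phi <- (p$stroke_amplitude_Phi / 2) * cos(wtph) * DEG2RAD
  theta <- p$deviation_amplitude * sin(2 * wtph) * DEG2RAD
  alpha <- p$incidence_profile(phase %% 1) * DEG2RAD
  if (length(alpha) == 1L) alpha <- rep(alpha, nfr)

  basis <- stroke_basis(p$stroke_plane_angle * DEG2RAD)
  th_body <- rbind(th1 = c(0, 0, 0), th2 = c(6, 0, 0), th3 = c(0, 5, 0))
  wb_body <- c(0, 3, 1)
  te_pos <- p$te_chord_positions
  amps <- p$te_deflection_amplitudes

  pts <- array(NA_real_, dim = c(nfr, 10L, 3L),
               dimnames = list(NULL, wing_point_labels(), c("x", "y", "z")))
  defl_truth <- matrix(0, nfr, 4L, dimnames = list(NULL, rownames(te_pos)))
  prev_sign <- 1
  for (k in seq_len(nfr)) {
    s <- span_vector(phi[k], theta[k], basis)
    cf <- chord_frame(s, basis)
    ch <- cos(alpha[k]) * cf$p + sin(alpha[k]) * cf$q
    n_w <- cos(alpha[k]) * cf$q - sin(alpha[k]) * cf$p  # unit normal s x ch
    # orient the normal toward the instantaneous wing-motion direction
    motion <- sign(sin(wtph[k])) * cf$p
    dot <- sum(n_w * motion)
    sgn <- if (abs(dot) < 1e-12) prev_sign else sign(dot)
    prev_sign <- sgn
    n_or <- sgn * n_w

    shift <- 1000 * p$body_velocity * times[k]  # m/s -> mm
    pts[k, 1:3, ] <- sweep(th_body, 2L, shift, `+`)
    pts[k, "wb", ] <- wb_body + shift
    pts[k, "mj", ] <- wb_body + R * (p$mj_position[1L] * s + p$mj_position[2L] * ch) + shift
    pts[k, "wt", ] <- wb_body + R * s + shift
    mag <- abs(sin(wtph[k]))
    for (j in rownames(te_pos)) {
      defl_truth[k, j] <- amps[[j]] * mag
      pts[k, j, ] <- wb_body + R * (te_pos[j, 1L] * s + te_pos[j, 2L] * ch) +
        R * defl_truth[k, j] * n_or + shift
    }
  }

  if (p$noise_sigma > 0) {
    pts <- pts + with_private_seed(p$seed,
      array(stats::rnorm(length(pts), 0, p$noise_sigma), dim = dim(pts)))
  }

  out <- list(times = times, points = pts,
              ground_truth = list(flapping_deg = phi * RAD2DEG,
                                  deviation_deg = theta * RAD2DEG,
                                  incidence_deg = alpha * RAD2DEG,
                                  deflection = defl_truth,
                                  stroke_plane_deg = p$stroke_plane_angle,
                                  frequency_hz = f,
                                  wing_length_R = R),
              params = p)
  class(out) <- "flight_recording"
  out
}

#' @export
print.flight_recording <- function(x, ...) {
  cat(sprintf("<flight_recording> %d frames, %.0f Hz sampling, %d labelled points\n",
              length(x$times), 1 / diff(x$times[1:2]), dim(x$points)[2L]))
  cat(sprintf("  wingbeat %.1f Hz, wing length %.1f mm, noise sd %.3g mm\n",
              x$params$frequency_f, x$params$wing_length_R, x$params$noise_sigma))
  invisible(x)
}
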