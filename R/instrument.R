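#' Dual-PEM polarimeter configuration
#'
#' Geometry and drive parameters of the dual photoelastic-modulator (PEM)
#' polarimeter. The optic axis of PEM2 defines the x-axis of the polarimeter
#' coordinate system; `alpha` is the angle of the PEM1 optic axis and `beta`
#' the angle of the analyser transmission axis, both from the x-axis.
#'
#' Defaults follow the instrument geometry this package models: alpha = 45
#' degrees, beta = 23 degrees, PEM head frequencies 50 and 42 (arbitrary time
#' units mirroring 50 kHz / 42 kHz heads), and peak retardation amplitudes at
#' 2.405 rad, the first zero of the Bessel function J0, which removes the
#' retardance-dependent DC terms — standard dual-PEM practice.
#'
#' @param alpha PEM1 optic-axis angle from the x-axis, radians.
#' @param beta analyser transmission-axis angle from the x-axis, radians.
#' @param f1,f2 PEM resonant frequencies (arbitrary units); must be distinct
#'   and positive.
#' @param A1,A2 PEM peak retardation amplitudes, radians; must be positive.
#' @param wavelength_nm illumination wavelength in nm (metadata only).
#' @return An object of class `"polarimeter_config"`.
#' @export
polarimeter_config <- function(alpha = pi / 4, beta = 23 * pi / 180,
                               f1 = 50, f2 = 42,
                               A1 = 2.405, A2 = 2.405,
                               wavelength_nm = 530) {
  stopifnot(is.numeric(alpha), is.numeric(beta))
  if (!(f1 > 0 && f2 > 0)) stop("PEM frequencies must be positive")
  if (f1 == f2) stop("PEM frequencies must be distinct")
  if (!(A1 > 0 && A2 > 0)) stop("PEM amplitudes must be positive")
  structure(list(alpha = alpha, beta = beta, f1 = f1, f2 = f2,
                 A1 = A1, A2 = A2, wavelength_nm = wavelength_nm),
            class = "polarimeter_config")
}

#' @export
print.polarimeter_config <- function(x, ...) {
  cat("Dual-PEM polarimeter configuration\n")
  cat(sprintf("  PEM1: axis %.2f deg, f1 = %g, A1 = %.4g rad\n",
              x$alpha * 180 / pi, x$f1, x$A1))
  cat(sprintf("  PEM2: axis 0 deg (defines x-axis), f2 = %g, A2 = %.4g rad\n",
              x$f2, x$A2))
  cat(sprintf("  Analyser: %.2f deg; wavelength %g nm\n",
              x$beta * 180 / pi, x$wavelength_nm))
  invisible(x)
}

#' Construct a Stokes polarisation state
#'
#' @param I,Q,U,V Stokes components (intensity units). For physical light
#'   `Q^2 + U^2 + V^2 <= I^2`; a warning is emitted when this is violated
#'   beyond numerical tolerance.
#' @return Numeric vector of length 4 with class `"polarisation_state"`.
#' @export
polarisation_state <- function(I, Q = 0, U = 0, V = 0) {
  if (I < 0) stop("Stokes I must be non-negative")
  p2 <- Q^2 + U^2 + V^2
  if (p2 > I^2 * (1 + 1e-9) + 1e-12)
    warning("unphysical Stokes vector: Q^2+U^2+V^2 > I^2")
  structure(c(I = I, Q = Q, U = U, V = V), class = "polarisation_state")
}

#' Fully polarised state from azimuth and ellipticity
#'
#' Builds the unit-intensity Stokes vector of a fully polarised beam with
#' polarisation azimuth `azimuth` and ellipticity angle `ellipticity`:
#' `(1, cos2e cos2a, cos2e sin2a, sin2e)`. `ellipticity = pi/4` gives
#' right-circular light `(1, 0, 0, 1)`.
#'
#' @param ellipticity ellipticity angle in radians, in `[-pi/4, pi/4]`.
#' @param azimuth polarisation azimuth in radians.
#' @param I total intensity (default 1).
#' @return A `"polarisation_state"`.
#' @export
elliptical_state <- function(ellipticity, azimuth = 0, I = 1) {
  if (abs(ellipticity) > pi / 4 + 1e-12)
    stop("ellipticity angle must lie in [-pi/4, pi/4]")
  polarisation_state(I,
                     I * cos(2 * ellipticity) * cos(2 * azimuth),
                     I * cos(2 * ellipticity) * sin(2 * azimuth),
                     I * sin(2 * ellipticity))
}

#' Demodulated harmonic signal set
#'
#' Container for the four demodulated signals of the dual-PEM polarimeter:
#' the DC level `S_DC`, the second-harmonic amplitudes `S_QU1` (at 2 f1) and
#' `S_QU2` (at 2 f2), and the first-harmonic amplitude `S_v` (at f1). Each
#' field may be a scalar or a pixel array; all must share one shape.
#'
#' @param S_DC,S_QU1,S_QU2,S_v numeric scalars or arrays of one common shape.
#' @return An object of class `"harmonic_signals"` (a named list).
#' @export
harmonic_signals <- function(S_DC, S_QU1, S_QU2, S_v) {
  dims <- lapply(list(S_DC, S_QU1, S_QU2, S_v), function(x) dim(x) %||% length(x))
  if (length(unique(vapply(dims, paste, collapse = ",", ""))) != 1L)
    stop("all signal planes must share one shape")
  structure(list(S_DC = S_DC, S_QU1 = S_QU1, S_QU2 = S_QU2, S_v = S_v),
            class = "harmonic_signals")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.harmonic_signals <- function(x, ...) {
  n <- length(x$S_DC)
  if (n == 1L) {
    cat(sprintf("Harmonic signals: S_DC = %.6g, S_QU1 = %.6g, S_QU2 = %.6g, S_v = %.6g\n",
                x$S_DC, x$S_QU1, x$S_QU2, x$S_v))
  } else {
    cat(sprintf("Harmonic signal stack: %s pixels per plane\n",
                paste(dim(x$S_DC) %||% n, collapse = " x ")))
  }
  invisible(x)
}

## Signal vector ordering used throughout (matches the calibration relation
## (I,Q,U,V) = K (S_DC, S_QU1, S_QU2, S_v)).
signal_vector <- function(sig) c(sig$S_DC, sig$S_QU1, sig$S_QU2, sig$S_v)

#' Instantaneous detector intensity of the dual-PEM chain
#'
#' Propagates a Stokes state through the time-varying Mueller chain
#' analyser(beta) . PEM2(delta2(t), axis 0) . PEM1(delta1(t), axis alpha),
#' with `delta_i(t) = A_i sin(2 pi f_i t)`, and returns the detected
#' intensity (first Stokes component). The PEMs shift polarisation-dependent
#' terms to harmonics of their resonant frequencies.
#'
#' @param state a `"polarisation_state"` or numeric length-4 Stokes vector.
#' @param cfg a [polarimeter_config()].
#' @param t time, scalar or vector (t >= 0).
#' @return Intensity, same length as `t`; non-negative for physical input.
#' @export
detector_intensity <- function(state, cfg, t) {
  stopifnot(inherits(cfg, "polarimeter_config"))
  if (any(t < 0)) stop("t must be non-negative")
  s <- unclass(state)
  d1 <- cfg$A1 * sin(2 * pi * cfg$f1 * t)
  d2 <- cfg$A2 * sin(2 * pi * cfg$f2 * t)
  ## analyser row combined with PEM2 (axis 0), then PEM1 at alpha, all
  ## vectorised over t
  cb <- cos(2 * cfg$beta); sb <- sin(2 * cfg$beta)
  ## w(t) = 0.5 * (1, cb, sb cos d2, sb sin d2) is the detection row after
  ## the analyser and PEM2
  ca <- cos(2 * cfg$alpha); sa <- sin(2 * cfg$alpha)
  ## PEM1 at alpha applied to s: rotate into PEM1 frame, retard, rotate back
  q1 <- ca * s[2] + sa * s[3]
  u1 <- -sa * s[2] + ca * s[3]
  u1d <- u1 * cos(d1) + s[4] * sin(d1)
  v1d <- -u1 * sin(d1) + s[4] * cos(d1)
  Qs <- ca * q1 - sa * u1d
  Us <- sa * q1 + ca * u1d
  0.5 * (s[1] + cb * Qs + sb * (Us * cos(d2) + v1d * sin(d2)))
}

## Smallest common period of the two PEM drives: T with T*f1 and T*f2 both
## integers, via a continued-fraction rational approximation of f2/f1.
common_period <- function(f1, f2, max_den = 10000L, tol = 1e-9) {
  r <- f2 / f1
  ## continued fraction convergents
  a <- r; p0 <- 1; q0 <- 0; p1 <- floor(a); q1 <- 1
  for (i in 1:64) {
    if (abs(p1 / q1 - r) < tol) break
    a <- 1 / (a - floor(a))
    p2 <- floor(a) * p1 + p0
    q2 <- floor(a) * q1 + q0
    p0 <- p1; q0 <- q1; p1 <- p2; q1 <- q2
    if (q1 > max_den) break
  }
  if (abs(p1 / q1 - r) >= tol)
    stop("PEM frequencies are not commensurate: no common period found")
  q1 / f1  # then T*f2 = p1, an integer
}

#' Simulate a sampled detector time series
#'
#' Samples [detector_intensity()] uniformly over an integer number of common
#' periods of the two PEM drives (endpoint excluded), as required by
#' [lockin_demodulate()].
#'
#' @param state input Stokes state.
#' @param cfg a [polarimeter_config()]; `f1/f2` must be rational.
#' @param n_samples samples per common period.
#' @param periods integer number of common periods.
#' @return List with fields `t`, `x`, `period`, `cfg`, class `"pem_series"`.
#' @export
simulate_intensity_series <- function(state, cfg, n_samples = 8192L, periods = 1L) {
  T0 <- common_period(cfg$f1, cfg$f2)
  n <- as.integer(n_samples) * as.integer(periods)
  t <- seq(0, T0 * periods, length.out = n + 1L)[seq_len(n)]
  structure(list(t = t, x = detector_intensity(state, cfg, t),
                 period = T0, cfg = cfg),
            class = "pem_series")
}

#' Lock-in demodulation of a detector time series
#'
#' Recovers the four harmonic signals by multiplication with reference
#' waveforms and averaging, the numerical analogue of phase-sensitive
#' (lock-in) detection: `S_DC` is the time average; `S_QU1`, `S_QU2` are
#' in-phase amplitudes against `cos(2 pi (2 f1) t)` and `cos(2 pi (2 f2) t)`;
#' `S_v` against `sin(2 pi f1 t)`; each amplitude is twice the mean product.
#'
#' The series must cover exactly an integer number of common periods of the
#' two drives and be sampled with at least 20 samples per cycle of the
#' fastest demodulated harmonic.
#'
#' @param series a `"pem_series"` from [simulate_intensity_series()], or a
#'   list with numeric `t` and `x` of equal length.
#' @param cfg a [polarimeter_config()]; defaults to `series$cfg`.
#' @return A [harmonic_signals()] object.
#' @export
lockin_demodulate <- function(series, cfg = series$cfg) {
  if (is.null(cfg)) stop("a polarimeter_config is required")
  t <- series$t; x <- series$x
  if (length(t) < 2L || length(t) != length(x))
    stop("series must provide equal-length t and x")
  T0 <- common_period(cfg$f1, cfg$f2)  # errors if non-commensurate
  dt <- t[2] - t[1]
  span <- dt * length(t)
  k <- span / T0
  if (abs(k - round(k)) > 1e-6 || round(k) < 1)
    stop("series must cover an integer number (>= 1) of common periods")
  fmax <- 2 * max(cfg$f1, cfg$f2)
  if (1 / (dt * fmax) < 20)
    stop("sampling too sparse: need >= 20 samples per cycle of the fastest harmonic")
  w1 <- 2 * pi * cfg$f1 * t
  w2 <- 2 * pi * cfg$f2 * t
  harmonic_signals(S_DC  = mean(x),
                   S_QU1 = 2 * mean(x * cos(2 * w1)),
                   S_QU2 = 2 * mean(x * cos(2 * w2)),
                   S_v   = 2 * mean(x * sin(w1)))
}

## Bilinear coefficient matrix C of the detector intensity:
## I(d1, d2) = sum_{p,q} C[p,q] b_p(d1) b_q(d2), b = (1, cos, sin).
## Obtained exactly by evaluating the static Mueller chain at 9 retardance
## pairs; the intensity is degree <= 1 in each of cos/sin of d1 and d2.
harmonic_coefficients <- function(state, cfg) {
  s <- unclass(state)
  pol <- mueller_polariser(cfg$beta)
  grid <- c(0, 1, -1)
  Imat <- matrix(0, 3, 3)
  for (i in 1:3) for (j in 1:3) {
    M <- pol %*% mueller_retarder(grid[j], 0) %*%
      mueller_retarder(grid[i], cfg$alpha)
    Imat[i, j] <- drop(M[1, ] %*% s)
  }
  B <- rbind(c(1, 1, 0),
             c(1, cos(1), sin(1)),
             c(1, cos(1), -sin(1)))
  Bi <- solve(B)
  Bi %*% Imat %*% t(Bi)
}

## Warn when low-order PEM harmonic combinations land on a demodulation
## reference frequency, which would invalidate the truncated Bessel series.
check_harmonic_coincidence <- function(cfg, max_order = 8L, tol = 1e-9) {
  refs <- c(cfg$f1, 2 * cfg$f1, 2 * cfg$f2)
  for (a in 1:max_order) for (b in 1:max_order) {
    f <- c(abs(a * cfg$f1 - b * cfg$f2), a * cfg$f1 + b * cfg$f2)
    if (any(abs(outer(f, refs, "-")) < tol))
      warning(sprintf("PEM harmonic combination (%d f1, %d f2) coincides with a demodulation reference; analytic harmonics may be inaccurate", a, b))
  }
  invisible(NULL)
}

#' Analytic harmonic amplitudes via the Bessel (Jacobi-Anger) expansion
#'
#' Independent closed-form oracle for the demodulated signals. The detector
#' intensity is bilinear in `(1, cos d1, sin d1)` and `(1, cos d2, sin d2)`;
#' with `d_i(t) = A_i sin(2 pi f_i t)` the Jacobi-Anger expansion
#' `cos(A sin wt) = J0(A) + 2 sum J_{2k}(A) cos(2k wt)` and
#' `sin(A sin wt) = 2 sum J_{2k+1}(A) sin((2k+1) wt)` yields the DC, f1,
#' 2 f1 and 2 f2 line amplitudes in terms of Bessel functions J0, J1, J2.
#' Cross-harmonic coincidences below order 8 are checked and warned about.
#'
#' Each returned signal is a linear functional of the input Stokes vector;
#' see [signal_matrix()] for the induced 4x4 map.
#'
#' @param state input Stokes state.
#' @param cfg a [polarimeter_config()].
#' @return A [harmonic_signals()] object.
#' @export
analytic_harmonics <- function(state, cfg) {
  check_harmonic_coincidence(cfg)
  C <- harmonic_coefficients(state, cfg)
  J0a <- besselJ(cfg$A1, 0); J0b <- besselJ(cfg$A2, 0)
  J1a <- besselJ(cfg$A1, 1)
  J2a <- besselJ(cfg$A1, 2); J2b <- besselJ(cfg$A2, 2)
  harmonic_signals(
    S_DC  = C[1, 1] + C[2, 1] * J0a + C[1, 2] * J0b + C[2, 2] * J0a * J0b,
    S_QU1 = 2 * J2a * (C[2, 1] + C[2, 2] * J0b),
    S_QU2 = 2 * J2b * (C[1, 2] + C[2, 2] * J0a),
    S_v   = 2 * J1a * (C[3, 1] + C[3, 2] * J0b))
}

#' Signal-from-Stokes response matrix of the instrument
#'
#' The 4x4 matrix `A` such that `(S_DC, S_QU1, S_QU2, S_v) = A (I, Q, U, V)`
#' for the configured instrument, assembled column-wise from
#' [analytic_harmonics()] applied to the Stokes basis vectors. Its inverse is
#' the ground-truth calibration matrix, see [true_k_matrix()].
#'
#' @param cfg a [polarimeter_config()].
#' @return A 4x4 numeric matrix with rows named after the signals.
#' @export
signal_matrix <- function(cfg) {
  A <- vapply(1:4, function(j) {
    e <- numeric(4); e[j] <- 1
    signal_vector(suppressWarnings(analytic_harmonics(e, cfg)))
  }, numeric(4))
  dimnames(A) <- list(c("S_DC", "S_QU1", "S_QU2", "S_v"),
                      c("I", "Q", "U", "V"))
  check_harmonic_coincidence(cfg)
  A
}
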