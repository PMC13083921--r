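#' Mueller matrix of a rotation of the Stokes coordinate frame
#'
#' Rotates the linear-polarisation components (Q, U) of a Stokes vector into a
#' frame rotated by `angle` about the propagation axis. Because Q and U
#' transform at twice the physical angle, the matrix mixes them by `2 * angle`.
#' Used to place optical elements at arbitrary orientations via
#' \eqn{M(\theta) = R(-\theta) \, M(0) \, R(\theta)}.
#'
#' @param angle rotation angle in radians.
#' @return A 4x4 numeric matrix. `mueller_rotator(0)` is the identity and
#'   `mueller_rotator(a) %*% mueller_rotator(b)` equals `mueller_rotator(a + b)`.
#' @export
mueller_rotator <- function(angle) {
  c2 <- cos(2 * angle)
  s2 <- sin(2 * angle)
  matrix(c(1,  0,   0,  0,
           0,  c2,  s2, 0,
           0, -s2,  c2, 0,
           0,  0,   0,  1), 4, 4, byrow = TRUE)
}

#' Mueller matrix of an ideal linear retarder
#'
#' Linear retarder with retardance `delta` and fast axis at `angle` from the
#' x-axis, built as the frame-rotated axis-aligned retarder. With `angle`
#' equal to the sample optic-axis orientation this reproduces, entry by entry,
#' the polarised (sigma = 1) uniaxial sample matrix of [sample_mueller()].
#'
#' @param delta retardance in radians.
#' @param angle fast-axis angle in radians (default 0).
#' @return A 4x4 numeric matrix.
#' @seealso [sample_mueller()] for the depolarising sample model.
#' @export
mueller_retarder <- function(delta, angle = 0) {
  cd <- cos(delta)
  sd <- sin(delta)
  m0 <- matrix(c(1, 0, 0,   0,
                 0, 1, 0,   0,
                 0, 0, cd,  sd,
                 0, 0, -sd, cd), 4, 4, byrow = TRUE)
  if (angle == 0) return(m0)
  mueller_rotator(-angle) %*% m0 %*% mueller_rotator(angle)
}

#' Mueller matrix of an ideal linear polariser
#'
#' Ideal linear polarisation analyser with transmission axis at `angle` from
#' the x-axis. The matrix is idempotent and its output is fully polarised;
#' unpolarised input is transmitted with intensity 1/2 (Malus average).
#'
#' @param angle transmission-axis angle in radians.
#' @return A 4x4 numeric matrix.
#' @export
mueller_polariser <- function(angle) {
  a <- c(1, cos(2 * angle), sin(2 * angle), 0)
  0.5 * tcrossprod(a)
}
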