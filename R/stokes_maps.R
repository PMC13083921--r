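#' Per-pixel Stokes image
#'
#' Container for the four Stokes parameter planes of an acquisition, with
#' sample-plane spatial metadata. All derived polarisation maps start here.
#'
#' @param I,Q,U,V numeric matrices of one common shape (arbitrary intensity
#'   units).
#' @param pixel_size_um sample-plane micrometres per pixel (> 0).
#' @param magnification objective magnification label (e.g. `"40x"`).
#' @return An object of class `"stokes_image"`.
#' @export
stokes_image <- function(I, Q, U, V, pixel_size_um = 1 / 6.17,
                         magnification = "40x") {
  planes <- list(I = as.matrix(I), Q = as.matrix(Q),
                 U = as.matrix(U), V = as.matrix(V))
  d <- dim(planes$I)
  if (!all(vapply(planes, function(p) identical(dim(p), d), logical(1))))
    stop("all four Stokes planes must share one shape")
  if (!(pixel_size_um > 0)) stop("pixel_size_um must be positive")
  structure(c(planes, list(pixel_size_um = pixel_size_um,
                           magnification = magnification)),
            class = "stokes_image")
}

#' @export
print.stokes_image <- function(x, ...) {
  cat(sprintf("Stokes image: %d x %d pixels, %.4g um/pixel (%s)\n",
              nrow(x$I), ncol(x$I), x$pixel_size_um, x$magnification))
  cat(sprintf("  I in [%.4g, %.4g]; max degree of polarisation %.4g\n",
              min(x$I), max(x$I),
              max(sqrt(x$Q^2 + x$U^2 + x$V^2) / pmax(x$I, .Machine$double.xmin))))
  invisible(x)
}

#' @export
plot.stokes_image <- function(x, ...) {
  op <- graphics::par(mfrow = c(2, 2), mar = c(1, 1, 2, 1))
  on.exit(graphics::par(op))
  for (p in c("I", "Q", "U", "V")) {
    graphics::image(t(x[[p]])[, nrow(x[[p]]):1], axes = FALSE, main = p,
                    col = grDevices::hcl.colors(64, "viridis"), ...)
  }
  invisible(x)
}

#' Normalised Stokes components
#'
#' Normalises by the polarised intensity `Ip = sqrt(Q^2 + U^2 + V^2)`:
#' `i = I/Ip`, `q = Q/Ip`, `u = U/Ip`, `v = V/Ip`, so that
#' `q^2 + u^2 + v^2 = 1` wherever defined — applicable to any state with a
#' nonzero polarised part. Pixels with `Ip` at or below `eps_ip` (default
#' `1e-12 * max(I)`) are masked (set `NA` and flagged), not silently
#' NaN-propagated, so downstream ROI statistics stay well defined.
#'
#' @param img a [stokes_image()] (or list with I, Q, U, V arrays).
#' @param eps_ip absolute threshold on `Ip` below which a pixel is masked;
#'   default `1e-12 * max(abs(I))`.
#' @return A list of class `"normalised_stokes"`: planes `i, q, u, v`, `Ip`,
#'   logical `mask` (TRUE = undefined), and `n_masked`.
#' @export
normalise_stokes <- function(img, eps_ip = NULL) {
  Ip <- sqrt(img$Q^2 + img$U^2 + img$V^2)
  if (is.null(eps_ip)) eps_ip <- 1e-12 * max(abs(img$I))
  mask <- Ip <= eps_ip
  div <- ifelse(mask, NA_real_, Ip)
  structure(list(i = img$I / div, q = img$Q / div, u = img$U / div,
                 v = img$V / div, Ip = Ip, mask = mask,
                 n_masked = sum(mask)),
            class = "normalised_stokes")
}

#' Ellipticity angle map
#'
#' Per-pixel ellipticity angle
#' `epsilon = 0.5 * asin(V / sqrt(Q^2 + U^2 + V^2))`, in `[-pi/4, pi/4]`:
#' 0 for linear light, +/- pi/4 for circular. Masked (NA) where the
#' polarised intensity vanishes.
#'
#' @inheritParams normalise_stokes
#' @return Numeric matrix of angles in radians.
#' @export
ellipticity_map <- function(img, eps_ip = NULL) {
  ns <- normalise_stokes(img, eps_ip)
  0.5 * asin(pmax(pmin(ns$v, 1), -1))
}

#' Polarisation azimuthal angle map
#'
#' Per-pixel azimuth `theta = 0.5 * arctan(U / Q)`, evaluated with the
#' two-argument arctangent `atan2(U, Q)` so the full `(-pi/2, pi/2]` range
#' is covered and `Q = 0` is handled; the single-argument form is quadrant
#' ambiguous. Masked where Q and U both vanish.
#'
#' @param img a [stokes_image()].
#' @param eps absolute threshold below which Q and U count as zero; default
#'   `1e-12 * max(|Q|, |U|)`.
#' @return Numeric matrix of angles in radians in `(-pi/2, pi/2]`.
#' @export
azimuth_map <- function(img, eps = NULL) {
  if (is.null(eps)) eps <- 1e-12 * max(abs(img$Q), abs(img$U))
  th <- 0.5 * atan2(img$U, img$Q)
  th[abs(img$Q) <= eps & abs(img$U) <= eps] <- NA_real_
  th
}

#' Degree of polarisation and depolarisation maps
#'
#' `dop_map` computes `P = sqrt(Q^2 + U^2 + V^2) / I`, the polarised
#' fraction of the intensity; `depolarisation_map` computes
#' `Dp = sqrt(1 - P^2)`, the per-pixel measure of polarisation loss from
#' microstructural scattering. Noise can push measured P marginally above 1;
#' such pixels are clamped to 1 before the square root and counted in the
#' `"n_clamped"` attribute so Dp stays real. Pixels with `I <= 0` are masked.
#'
#' @param img a [stokes_image()].
#' @return Numeric matrix; `dop_map` additionally carries attribute
#'   `n_clamped`.
#' @export
dop_map <- function(img) {
  P <- sqrt(img$Q^2 + img$U^2 + img$V^2) / ifelse(img$I > 0, img$I, NA_real_)
  n_clamped <- sum(P > 1, na.rm = TRUE)
  P <- pmin(P, 1)
  attr(P, "n_clamped") <- n_clamped
  P
}

#' @rdname dop_map
#' @export
depolarisation_map <- function(img) {
  P <- dop_map(img)
  Dp <- sqrt(1 - P^2)
  attr(Dp, "n_clamped") <- attr(P, "n_clamped")
  Dp
}

#' All derived polarisation maps of a Stokes image
#'
#' Convenience wrapper returning the normalised components together with the
#' ellipticity, azimuth, degree-of-polarisation, depolarisation and polarised
#' intensity maps.
#'
#' @inheritParams normalise_stokes
#' @return A list of class `"polarisation_maps"` with fields
#'   `i, q, u, v, Ip, epsilon, theta, P, Dp`, the undefined-pixel `mask`, and
#'   `diagnostics` (masked and clamped counts).
#' @export
polarisation_maps <- function(img, eps_ip = NULL) {
  ns <- normalise_stokes(img, eps_ip)
  P <- dop_map(img)
  structure(list(i = ns$i, q = ns$q, u = ns$u, v = ns$v, Ip = ns$Ip,
                 epsilon = ellipticity_map(img, eps_ip),
                 theta = azimuth_map(img),
                 P = P, Dp = depolarisation_map(img),
                 mask = ns$mask,
                 pixel_size_um = img$pixel_size_um %||% NA_real_,
                 diagnostics = list(n_masked = ns$n_masked,
                                    n_clamped = attr(P, "n_clamped"))),
            class = "polarisation_maps")
}

#' @export
print.polarisation_maps <- function(x, ...) {
  cat(sprintf("Polarisation maps: %d x %d pixels (%d masked, %d P>1 clamped)\n",
              nrow(x$P), ncol(x$P), x$diagnostics$n_masked,
              x$diagnostics$n_clamped))
  cat(sprintf("  P in [%.3g, %.3g]; Dp in [%.3g, %.3g]\n",
              min(x$P, na.rm = TRUE), max(x$P, na.rm = TRUE),
              min(x$Dp, na.rm = TRUE), max(x$Dp, na.rm = TRUE)))
  invisible(x)
}
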