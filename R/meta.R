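#' Acquisition metadata
#'
#' Camera and objective parameters of an acquisition. Defaults describe the
#' high-magnification configuration: 6.5 um camera pixel pitch, 40x
#' objective, 6.17 pixel/um sample-plane sampling density, 530 nm LED
#' illumination. The 4x objective corresponds to 0.617 pixel/um.
#'
#' @param pitch_um camera pixel pitch in micrometres (> 0).
#' @param magnification objective magnification.
#' @param px_per_um sample-plane sampling density, pixels per um (> 0).
#' @param wavelength_nm illumination wavelength.
#' @param input_state illumination Stokes state record.
#' @return An object of class `"acquisition_meta"`.
#' @export
acquisition_meta <- function(pitch_um = 6.5, magnification = 40,
                             px_per_um = 6.17, wavelength_nm = 530,
                             input_state = c(1, 0, 0, 1)) {
  if (!(pitch_um > 0)) stop("pitch_um must be positive")
  if (!(px_per_um > 0)) stop("sampling density must be positive")
  structure(list(pitch_um = pitch_um, magnification = magnification,
                 px_per_um = px_per_um, wavelength_nm = wavelength_nm,
                 input_state = input_state),
            class = "acquisition_meta")
}

#' Physical field-of-view extent from pixel count and sampling density
#'
#' `extent = n_pixels / px_per_um`, optionally converted to millimetres.
#' E.g. 2561 pixels at 6.17 pixel/um is 415.1 um; the same pixel count at a
#' tenfold lower density (0.617 pixel/um, the 4x objective) is 4.151 mm.
#'
#' @param n_pixels pixels along the axis (> 0).
#' @param px_per_um sampling density in pixels per micrometre (> 0).
#' @param unit `"um"` or `"mm"`.
#' @return Physical extent in the requested unit.
#' @export
fov_from_sampling <- function(n_pixels, px_per_um, unit = c("um", "mm")) {
  unit <- match.arg(unit)
  if (!(n_pixels > 0) || !(px_per_um > 0))
    stop("n_pixels and px_per_um must be positive")
  ext <- n_pixels / px_per_um
  if (unit == "mm") ext / 1000 else ext
}
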