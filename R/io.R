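## Interchange formats: multi-page 32-bit float TIFF for images (page order
## documented in the description tag), CSV for calibration sets / ROI specs /
## results, YAML for K matrices and polarimeter / input-state configs.
## All writes go through a temp file + rename, so interrupted runs never
## leave truncated outputs.

atomic_write_text <- function(path, writer) {
  tmp <- paste0(path, ".tmp", Sys.getpid())
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  writer(tmp)
  if (!file.rename(tmp, path)) stop("could not move temporary file to ", path)
  invisible(path)
}

parse_desc_field <- function(desc, key) {
  if (is.null(desc)) return(NULL)
  m <- regmatches(desc, regexec(paste0(key, "=([^;]+)"), desc))[[1]]
  if (length(m) < 2) NULL else m[2]
}

#' Write / read a Stokes image as a 4-page float TIFF
#'
#' Page order I, Q, U, V (recorded, with the pixel size, in the TIFF
#' description tag). Reading a file with a different page count is an
#' explicit format error.
#'
#' @param img a [stokes_image()].
#' @param path file path.
#' @return `write_stokes_tiff` returns `path` invisibly; `read_stokes_tiff`
#'   returns a [stokes_image()].
#' @export
write_stokes_tiff <- function(img, path) {
  stopifnot(inherits(img, "stokes_image"))
  write_float_tiff(list(img$I, img$Q, img$U, img$V), path,
                   description = sprintf(
                     "stokespol StokesImage; pages=I,Q,U,V; pixel_size_um=%.10g; magnification=%s; units=AU",
                     img$pixel_size_um, img$magnification))
}

#' @rdname write_stokes_tiff
#' @export
read_stokes_tiff <- function(path) {
  pg <- read_float_tiff(path)
  if (length(pg) != 4)
    stop(sprintf("expected a 4-page Stokes TIFF (pages I,Q,U,V); '%s' has %d page(s)",
                 path, length(pg)))
  desc <- attr(pg, "description")
  px <- as.numeric(parse_desc_field(desc, "pixel_size_um") %||% (1 / 6.17))
  mag <- parse_desc_field(desc, "magnification") %||% "unknown"
  stokes_image(pg[[1]], pg[[2]], pg[[3]], pg[[4]], px, mag)
}

#' Write / read a single scalar map as a one-page float TIFF
#'
#' @param map numeric matrix.
#' @param path file path.
#' @param units unit string recorded in the description tag (e.g. `"rad"`).
#' @return `write_map_tiff` returns `path` invisibly; `read_map_tiff`
#'   returns the matrix with attribute `units`.
#' @export
write_map_tiff <- function(map, path, units = "dimensionless") {
  write_float_tiff(as.matrix(map), path,
                   description = sprintf("stokespol map; units=%s", units))
}

#' @rdname write_map_tiff
#' @export
read_map_tiff <- function(path) {
  pg <- read_float_tiff(path)
  if (length(pg) != 1)
    stop(sprintf("expected a one-page map TIFF; '%s' has %d pages", path, length(pg)))
  m <- pg[[1]]
  attr(m, "units") <- parse_desc_field(attr(pg, "description"), "units")
  m
}

#' Write / read a ground-truth sidecar (delta, gamma, sigma) TIFF
#'
#' Three pages: retardation (rad), optic-axis angle (rad), depolarisation
#' factor sigma.
#'
#' @param truth list with matrices `delta`, `gamma`, `sigma` (e.g. the
#'   `truth` of a [generate_phantom()] result).
#' @param path file path.
#' @return `write_truth_tiff` returns `path` invisibly; `read_truth_tiff`
#'   returns the list of three matrices.
#' @export
write_truth_tiff <- function(truth, path) {
  write_float_tiff(list(truth$delta, truth$gamma, truth$sigma), path,
                   description = "stokespol truth; pages=delta,gamma,sigma; units=rad,rad,dimensionless")
}

#' @rdname write_truth_tiff
#' @export
read_truth_tiff <- function(path) {
  pg <- read_float_tiff(path)
  if (length(pg) != 3)
    stop(sprintf("expected a 3-page truth TIFF (delta,gamma,sigma); '%s' has %d pages",
                 path, length(pg)))
  list(delta = pg[[1]], gamma = pg[[2]], sigma = pg[[3]])
}

#' Write / read a 4-page harmonic-signal acquisition TIFF
#'
#' Page order S_DC, S_QU1, S_QU2, S_v.
#'
#' @param signals a [harmonic_signals()] stack with matrix planes.
#' @param path file path.
#' @return `write_signals_tiff` returns `path` invisibly;
#'   `read_signals_tiff` returns a [harmonic_signals()] object.
#' @export
write_signals_tiff <- function(signals, path) {
  stopifnot(inherits(signals, "harmonic_signals"))
  write_float_tiff(lapply(signals[c("S_DC", "S_QU1", "S_QU2", "S_v")], as.matrix),
                   path,
                   description = "stokespol signals; pages=S_DC,S_QU1,S_QU2,S_v")
}

#' @rdname write_signals_tiff
#' @export
read_signals_tiff <- function(path) {
  pg <- read_float_tiff(path)
  if (length(pg) != 4)
    stop(sprintf("expected a 4-page signal TIFF (S_DC,S_QU1,S_QU2,S_v); '%s' has %d pages",
                 path, length(pg)))
  harmonic_signals(pg[[1]], pg[[2]], pg[[3]], pg[[4]])
}

#' Serialise / load a calibration matrix as YAML
#'
#' The eight named elements k1..k8.
#'
#' @param K a [k_matrix()] or `"k_calibration"` fit.
#' @param path file path.
#' @return `write_k_yaml` returns `path` invisibly; `read_k_yaml` a
#'   [k_matrix()].
#' @export
write_k_yaml <- function(K, path) {
  if (inherits(K, "k_calibration")) K <- K$kmat
  stopifnot(inherits(K, "k_matrix"))
  atomic_write_text(path, function(tmp)
    yaml::write_yaml(as.list(K$k), tmp, precision = 15))
}

#' @rdname write_k_yaml
#' @export
read_k_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  need <- paste0("k", 1:8)
  if (!all(need %in% names(y)))
    stop("K file must define elements k1..k8")
  do.call(k_matrix, y[need])
}

#' Read / write a calibration set CSV
#'
#' Columns `state_I, state_Q, state_U, state_V, S_DC, S_QU1, S_QU2, S_v`,
#' one calibration state per row.
#'
#' @param cal data.frame in that schema.
#' @param path file path.
#' @return `read_calibration_csv` returns the data.frame.
#' @export
write_calibration_csv <- function(cal, path) {
  atomic_write_text(path, function(tmp)
    utils::write.csv(cal, tmp, row.names = FALSE))
}

#' @rdname write_calibration_csv
#' @export
read_calibration_csv <- function(path) {
  cal <- utils::read.csv(path)
  cal_as_matrices(cal)  # validates columns
  cal
}

#' Read an ROI specification CSV
#'
#' Columns `label, cx, cy, side_um` (centres in pixels, side in
#' micrometres). Parse failures report the offending line.
#'
#' @param path file path.
#' @return A list of [roi_spec()] objects.
#' @export
read_roi_csv <- function(path) {
  df <- tryCatch(utils::read.csv(path),
                 error = function(e) stop("cannot parse ROI CSV: ", conditionMessage(e)))
  need <- c("label", "cx", "cy", "side_um")
  if (!all(need %in% names(df)))
    stop("ROI CSV must have columns ", paste(need, collapse = ", "))
  for (i in seq_len(nrow(df))) {
    bad <- !is.finite(df$cx[i]) || !is.finite(df$cy[i]) ||
      !is.finite(df$side_um[i]) || df$side_um[i] <= 0
    if (bad)
      stop(sprintf("ROI CSV line %d: invalid numeric fields (cx=%s, cy=%s, side_um=%s)",
                   i + 1L, df$cx[i], df$cy[i], df$side_um[i]))
  }
  lapply(seq_len(nrow(df)), function(i)
    roi_spec(df$label[i], df$cx[i], df$cy[i], df$side_um[i], "um"))
}

#' Read an input-state YAML file
#'
#' Accepts either explicit Stokes components (`I, Q, U, V`) or
#' `ellipticity_deg` (+ optional `azimuth_deg`) for a fully polarised state.
#'
#' @param path file path.
#' @return A [polarisation_state()].
#' @export
read_state_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  if (all(c("I", "Q", "U", "V") %in% names(y)))
    return(polarisation_state(y$I, y$Q, y$U, y$V))
  if ("ellipticity_deg" %in% names(y))
    return(elliptical_state(y$ellipticity_deg * pi / 180,
                            (y$azimuth_deg %||% 0) * pi / 180))
  stop("state file must define I,Q,U,V or ellipticity_deg")
}

#' Read a polarimeter configuration YAML file
#'
#' Human-facing angles are degrees (`alpha_deg`, `beta_deg`); amplitudes are
#' radians; missing keys fall back to the package defaults.
#'
#' @param path file path.
#' @return A [polarimeter_config()].
#' @export
read_polarimeter_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  polarimeter_config(
    alpha = (y$alpha_deg %||% 45) * pi / 180,
    beta = (y$beta_deg %||% 23) * pi / 180,
    f1 = y$pem1_freq %||% 50, f2 = y$pem2_freq %||% 42,
    A1 = y$pem1_amplitude_rad %||% 2.405,
    A2 = y$pem2_amplitude_rad %||% 2.405,
    wavelength_nm = y$wavelength_nm %||% 530)
}

#' Export a map as a colormapped PNG
#'
#' Simple visualisation export (viridis colormap, linear scaling between the
#' finite range limits).
#'
#' @param map numeric matrix.
#' @param path output PNG path.
#' @param zlim optional range; defaults to the finite data range.
#' @return Invisibly, `path`.
#' @export
write_map_png <- function(map, path, zlim = NULL) {
  map <- as.matrix(map)
  if (is.null(zlim)) zlim <- range(map, finite = TRUE)
  grDevices::png(path, width = ncol(map), height = nrow(map))
  op <- graphics::par(mar = c(0, 0, 0, 0))
  graphics::image(t(map)[, nrow(map):1, drop = FALSE], axes = FALSE,
                  zlim = zlim, col = grDevices::hcl.colors(256, "viridis"),
                  useRaster = TRUE)
  graphics::par(op)
  grDevices::dev.off()
  invisible(path)
}
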