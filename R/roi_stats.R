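#' Square region-of-interest specification
#'
#' Square ROI for quantitative map statistics, given by its centre (pixel
#' coordinates) and side length in micrometres or pixels. A 48.6 um side at
#' a sampling density of 0.617 pixel/um yields 30 x 30 = ~900 pixels.
#'
#' @param label group label for the ROI.
#' @param cx,cy centre, in pixel coordinates (column, row).
#' @param side side length (> 0).
#' @param side_unit `"um"` (default) or `"px"`.
#' @return An object of class `"roi_spec"`.
#' @export
roi_spec <- function(label, cx, cy, side, side_unit = c("um", "px")) {
  side_unit <- match.arg(side_unit)
  if (!(side > 0)) stop("ROI side must be positive")
  structure(list(label = as.character(label), cx = cx, cy = cy,
                 side = side, side_unit = side_unit),
            class = "roi_spec")
}

#' ROI side length in pixels
#'
#' Converts a physical side length to pixels at a given sampling density,
#' rounding to the nearest pixel.
#'
#' @param side_um side length in micrometres.
#' @param px_per_um sampling density, pixels per sample-plane micrometre.
#' @return Integer number of pixels.
#' @export
roi_side_pixels <- function(side_um, px_per_um) {
  if (!(side_um > 0) || !(px_per_um > 0))
    stop("side_um and px_per_um must be positive")
  as.integer(round(side_um * px_per_um))
}

#' Extract per-ROI value vectors from a scalar map
#'
#' Cuts square ROIs out of a map (e.g. retardation or depolarisation),
#' converting micrometre side lengths to pixels via the sampling density.
#' Masked (non-finite) pixels are excluded and their count reported per ROI.
#'
#' @param map numeric matrix.
#' @param specs a list of [roi_spec()] objects (or a single one).
#' @param px_per_um sampling density (pixels per micrometre); required when
#'   any ROI side is given in micrometres.
#' @return Named list of numeric vectors (one per ROI, named by label with
#'   a numeric suffix when labels repeat); each vector carries attributes
#'   `n_masked` and `label`.
#' @export
extract_rois <- function(map, specs, px_per_um = NULL) {
  map <- as.matrix(map)
  if (inherits(specs, "roi_spec")) specs <- list(specs)
  out <- vector("list", length(specs))
  labs <- character(length(specs))
  for (k in seq_along(specs)) {
    sp <- specs[[k]]
    stopifnot(inherits(sp, "roi_spec"))
    side_px <- if (sp$side_unit == "um") {
      if (is.null(px_per_um)) stop("px_per_um is required for ROI sides in um")
      roi_side_pixels(sp$side, px_per_um)
    } else as.integer(round(sp$side))
    half <- side_px / 2
    x0 <- as.integer(round(sp$cx - half + 0.5))
    y0 <- as.integer(round(sp$cy - half + 0.5))
    x1 <- x0 + side_px - 1L; y1 <- y0 + side_px - 1L
    if (x0 < 1 || y0 < 1 || x1 > ncol(map) || y1 > nrow(map))
      stop(sprintf("ROI '%s' extends outside the image", sp$label))
    vals <- as.vector(map[y0:y1, x0:x1])
    keep <- is.finite(vals)
    if (!any(keep)) stop(sprintf("ROI '%s' is fully masked", sp$label))
    v <- vals[!is.na(vals) & keep]
    attr(v, "n_masked") <- sum(!keep)
    attr(v, "label") <- sp$label
    out[[k]] <- v
    labs[k] <- sp$label
  }
  names(out) <- make.unique(labs)
  out
}

#' Mean, SD and n of ROI values
#'
#' Sample standard deviation (n - 1 denominator).
#'
#' @param values numeric vector (n >= 1).
#' @return Named numeric vector `c(mean, sd, n)`; `sd` is `NA` for n = 1.
#' @export
summarise_roi <- function(values) {
  if (length(values) < 1) stop("empty ROI value vector")
  c(mean = mean(values), sd = stats::sd(values), n = length(values))
}

#' Shapiro-Wilk normality test p-value
#'
#' Supported sample sizes are 3 to 5000. A constant vector has no defined
#' normality p-value and raises an error.
#'
#' @param values numeric vector.
#' @return The p-value.
#' @export
test_normality <- function(values) {
  n <- length(values)
  if (n < 3 || n > 5000)
    stop("Shapiro-Wilk requires 3 <= n <= 5000")
  stats::shapiro.test(values)$p.value
}

#' Compare two groups with a normality-gated test
#'
#' Reproduces the standard ROI-comparison protocol: Shapiro-Wilk normality
#' on each group at level `alpha_normality`; if both pass, a two-tailed
#' unpaired t-test (Welch by default), otherwise a two-sided Mann-Whitney U
#' (Wilcoxon rank-sum) test, exact for small untied samples. A group whose
#' normality test is undefined (constant values) is treated as non-normal.
#' Significance is flagged at p <= 0.05.
#'
#' @param a,b numeric value vectors (each n >= 3).
#' @param labels group labels, length 2.
#' @param alpha_normality Shapiro-Wilk gate level.
#' @param var_equal use the pooled-variance t-test instead of Welch.
#' @return An object of class `"group_comparison"`: labels, per-group n,
#'   mean, sd, `shapiro_p`, `test` name, `statistic`, `p_value`,
#'   `significant`.
#' @export
compare_groups <- function(a, b, labels = c("A", "B"),
                           alpha_normality = 0.05, var_equal = FALSE) {
  if (length(a) < 3 || length(b) < 3)
    stop("both groups need n >= 3")
  sw <- vapply(list(a, b), function(x)
    tryCatch(test_normality(x), error = function(e) NA_real_), numeric(1))
  normal <- !is.na(sw) & sw > alpha_normality
  if (all(normal)) {
    ht <- stats::t.test(a, b, var.equal = var_equal)
    test <- "t-test"
  } else {
    ht <- suppressWarnings(stats::wilcox.test(a, b))
    test <- "Mann-Whitney U"
    if (is.na(ht$p.value)) ht$p.value <- 1  # fully degenerate (all ties)
  }
  structure(list(labels = labels,
                 n = c(length(a), length(b)),
                 mean = c(mean(a), mean(b)),
                 sd = c(stats::sd(a), stats::sd(b)),
                 shapiro_p = sw,
                 test = test,
                 statistic = unname(ht$statistic),
                 p_value = ht$p.value,
                 significant = ht$p.value <= 0.05,
                 data = list(a = a, b = b)),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("Group comparison: %s (n=%d, mean %.4g, SD %.4g) vs %s (n=%d, mean %.4g, SD %.4g)\n",
              x$labels[1], x$n[1], x$mean[1], x$sd[1],
              x$labels[2], x$n[2], x$mean[2], x$sd[2]))
  cat(sprintf("  Shapiro-Wilk p: %.3g / %.3g -> %s\n",
              x$shapiro_p[1], x$shapiro_p[2], x$test))
  cat(sprintf("  statistic = %.4g, two-sided p = %.4g%s\n",
              x$statistic, x$p_value,
              if (x$significant) "  (significant at 0.05)" else ""))
  invisible(x)
}

#' @export
plot.group_comparison <- function(x, ...) {
  graphics::boxplot(x$data$a, x$data$b, names = x$labels, range = 1.5, ...)
  invisible(x)
}
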