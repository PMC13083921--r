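#' Per-pixel uniaxial birefringent sample parameters
#'
#' Ground-truth or estimated fields of the uniaxial sample model: phase
#' retardation `delta` (radians, principal value in `[0, pi]`), in-plane
#' optic-axis angle `gamma` (radians, defined modulo pi; meaningless where
#' `delta = 0`), and depolarisation factor `sigma = 1/P >= 1`.
#'
#' @param delta retardation matrix (rad), values in `[0, pi]`.
#' @param gamma optic-axis angle matrix (rad); recycled if scalar.
#' @param sigma depolarisation factor (>= 1); recycled if scalar.
#' @return An object of class `"sample_map"`.
#' @export
sample_map <- function(delta, gamma = 0, sigma = 1) {
  delta <- as.matrix(delta)
  if (length(gamma) == 1L) gamma <- array(gamma, dim(delta))
  if (length(sigma) == 1L) sigma <- array(sigma, dim(delta))
  gamma <- as.matrix(gamma); sigma <- as.matrix(sigma)
  if (!identical(dim(delta), dim(gamma)) || !identical(dim(delta), dim(sigma)))
    stop("delta, gamma and sigma must share one shape")
  if (any(delta < 0 | delta > pi + 1e-12))
    stop("delta must lie in [0, pi]")
  if (any(sigma < 1 - 1e-12)) stop("sigma must be >= 1")
  structure(list(delta = delta, gamma = gamma, sigma = sigma),
            class = "sample_map")
}

#' Mueller matrix of a uniaxial birefringent, depolarising sample
#'
#' The 4x4 matrix of a sample with in-plane optic axis at angle `gamma`
#' from the x-axis, phase retardation `delta_s`, and depolarisation factor
#' `sigma = 1/P`:
#' \preformatted{
#' [ sigma  0                          0                          0
#'   0      cos4g sin^2(d/2)+cos^2(d/2)  sin4g sin^2(d/2)          -sin2g sin d
#'   0      sin4g sin^2(d/2)          -cos4g sin^2(d/2)+cos^2(d/2)  cos2g sin d
#'   0      sin2g sin d               -cos2g sin d                  cos d     ]
#' }
#' With `sigma = 1` the lower-right 3x3 block is a proper rotation and the
#' matrix equals [mueller_retarder()] with fast axis at `gamma`.
#'
#' @param delta_s phase retardation (rad).
#' @param gamma optic-axis angle (rad).
#' @param sigma depolarisation factor, >= 1.
#' @return A 4x4 numeric matrix.
#' @export
sample_mueller <- function(delta_s, gamma = 0, sigma = 1) {
  if (sigma < 1 - 1e-12) stop("sigma must be >= 1")
  s2 <- sin(delta_s / 2)^2
  c2 <- cos(delta_s / 2)^2
  sd <- sin(delta_s)
  c2g <- cos(2 * gamma); s2g <- sin(2 * gamma)
  c4g <- cos(4 * gamma); s4g <- sin(4 * gamma)
  matrix(c(sigma, 0, 0, 0,
           0,  c4g * s2 + c2,  s4g * s2,      -s2g * sd,
           0,  s4g * s2,      -c4g * s2 + c2,  c2g * sd,
           0,  s2g * sd,      -c2g * sd,       cos(delta_s)),
         4, 4, byrow = TRUE)
}

#' Propagate a normalised Stokes state through a sample map
#'
#' Applies the sample Mueller model per pixel to a normalised input state
#' `(i, q, u, v)` (with `q^2 + u^2 + v^2 = 1`), returning the transmitted
#' normalised state. With `sigma = 1` the polarised part is rotated, so the
#' unit norm of `(q', u', v')` is preserved; the intensity component picks
#' up the factor sigma, which is what encodes the transmitted degree of
#' polarisation `P = 1/sigma` for fully polarised input.
#'
#' @param state list with numeric `i, q, u, v` (scalars or arrays matching
#'   the map shape); `i` defaults to 1 if absent.
#' @param map a [sample_map()].
#' @return List with fields `i, q, u, v` of the map's shape.
#' @export
propagate <- function(state, map) {
  stopifnot(inherits(map, "sample_map"))
  q <- state$q; u <- state$u; v <- state$v
  i <- state$i %||% 1
  shp <- dim(map$delta)
  chk <- function(x) {
    if (length(x) == 1L) return(x)
    if (!identical(dim(as.matrix(x)), shp))
      stop("state planes must be scalars or match the map shape")
    x
  }
  q <- chk(q); u <- chk(u); v <- chk(v); i <- chk(i)
  s2 <- sin(map$delta / 2)^2
  c2 <- cos(map$delta / 2)^2
  sd <- sin(map$delta)
  c2g <- cos(2 * map$gamma); s2g <- sin(2 * map$gamma)
  c4g <- cos(4 * map$gamma); s4g <- sin(4 * map$gamma)
  list(i = map$sigma * i,
       q = (c4g * s2 + c2) * q + (s4g * s2) * u - (s2g * sd) * v,
       u = (s4g * s2) * q + (-c4g * s2 + c2) * u + (c2g * sd) * v,
       v = (s2g * sd) * q - (c2g * sd) * u + cos(map$delta) * v)
}

#' Phase retardation from the circular-illumination relation
#'
#' Under perfectly circularly polarised illumination the transmitted
#' normalised circular component satisfies `v' = cos(delta_s)`, so
#' `delta_s = acos(v')`, the principal value in `[0, pi]`. Values pushed
#' outside `[-1, 1]` by noise are clamped and counted in the `"n_clamped"`
#' attribute.
#'
#' @param v_prime normalised transmitted circular component (scalar/array).
#' @return Retardation in radians, same shape, with attribute `n_clamped`.
#' @export
retardation_from_circular <- function(v_prime) {
  n_clamped <- sum(abs(v_prime) > 1, na.rm = TRUE)
  d <- acos(pmax(pmin(v_prime, 1), -1))
  attr(d, "n_clamped") <- n_clamped
  d
}

#' Optic-axis angle from the transmitted linear components
#'
#' Under circular illumination `q' = -sin(2 gamma) sin(delta_s)` and
#' `u' = cos(2 gamma) sin(delta_s)`, so `q'/u' = -tan(2 gamma)` and
#' `gamma = 0.5 * atan2(-q', u')`, reduced to `[0, pi)`. Where
#' `sin(delta_s) ~ 0` (both components below `tol_axis`) the axis is
#' undefined and masked.
#'
#' @param q_prime,u_prime transmitted normalised linear components.
#' @param tol_axis absolute threshold on `sqrt(q'^2 + u'^2)`; default
#'   `1e-6 * max` of that magnitude.
#' @return Angle in radians in `[0, pi)`, NA where undefined.
#' @export
axis_from_linear <- function(q_prime, u_prime, tol_axis = NULL) {
  mag <- sqrt(q_prime^2 + u_prime^2)
  if (is.null(tol_axis)) tol_axis <- 1e-6 * max(mag, na.rm = TRUE)
  g <- 0.5 * atan2(-q_prime, u_prime)
  g <- g %% pi
  g[mag <= tol_axis] <- NA_real_
  g
}

## Vectorised residuals and Jacobian of the three transmitted-component
## equations for unknowns (delta, gamma), given the known input (q, u, v).
biref_residuals <- function(d, g, q, u, v, qp, up, vp) {
  s2 <- sin(d / 2)^2; c2 <- cos(d / 2)^2; sd <- sin(d)
  c2g <- cos(2 * g); s2g <- sin(2 * g)
  c4g <- cos(4 * g); s4g <- sin(4 * g)
  list(r1 = (c4g * s2 + c2) * q + s4g * s2 * u - s2g * sd * v - qp,
       r2 = s4g * s2 * q + (-c4g * s2 + c2) * u + c2g * sd * v - up,
       r3 = s2g * sd * q - c2g * sd * u + cos(d) * v - vp)
}

biref_jacobian <- function(d, g, q, u, v) {
  s2 <- sin(d / 2)^2; sd <- sin(d); cd <- cos(d)
  c2g <- cos(2 * g); s2g <- sin(2 * g)
  c4g <- cos(4 * g); s4g <- sin(4 * g)
  hs <- sd / 2
  list(
    d1d = (c4g - 1) * hs * q + s4g * hs * u - s2g * cd * v,
    d2d = s4g * hs * q - (c4g + 1) * hs * u + c2g * cd * v,
    d3d = s2g * cd * q - c2g * cd * u - sd * v,
    d1g = -4 * s4g * s2 * q + 4 * c4g * s2 * u - 2 * c2g * sd * v,
    d2g = 4 * c4g * s2 * q + 4 * s4g * s2 * u - 2 * s2g * sd * v,
    d3g = 2 * c2g * sd * q + 2 * s2g * sd * u)
}

biref_cost <- function(d, g, q, u, v, qp, up, vp) {
  r <- biref_residuals(d, g, q, u, v, qp, up, vp)
  r$r1^2 + r$r2^2 + r$r3^2
}

#' Joint retardation and optic-axis inversion for arbitrary polarised input
#'
#' Solves the three transmitted-component equations for the two unknowns
#' `(delta_s, gamma)` per pixel by damped Gauss-Newton least squares, given
#' the input normalised state measured without the sample. For perfectly
#' circular input this coincides with [retardation_from_circular()] /
#' [axis_from_linear()]; for elliptical input it removes the
#' orientation-dependent bias that the circular-illumination shortcut
#' incurs.
#'
#' Starts from the circular-approximation estimates plus a small set of
#' optic-axis offsets and keeps the per-pixel best, so the periodic ambiguity
#' of the residual surface cannot trap the solver. Pixels that fail to reach
#' `tol` fall back to the circular-approximation value and are flagged.
#'
#' @param q_prime,u_prime,v_prime transmitted normalised components
#'   (scalars or arrays of one shape).
#' @param input normalised input state: numeric `c(q, u, v)` or a list with
#'   those fields (scalars).
#' @param max_iter maximum damped Gauss-Newton iterations.
#' @param tol convergence threshold on the parameter step (radians).
#' @param tol_delta retardation below which gamma is masked.
#' @return List of class `"biref_inversion"`: `delta`, `gamma` (NA where
#'   undefined), logical `converged`, `iterations`, and `cost` (final summed
#'   squared residual per pixel).
#' @export
retardation_full_inversion <- function(q_prime, u_prime, v_prime, input,
                                       max_iter = 80L, tol = 1e-12,
                                       tol_delta = 1e-8) {
  if (is.list(input)) input <- c(input$q, input$u, input$v)
  stopifnot(length(input) == 3)
  nrm <- sqrt(sum(input^2))
  if (abs(nrm - 1) > 1e-6)
    stop("input state must be normalised: q^2 + u^2 + v^2 = 1")
  input <- input / nrm
  q <- input[1]; u <- input[2]; v <- input[3]
  shp <- dim(v_prime)
  qp <- as.vector(q_prime); up <- as.vector(u_prime); vp <- as.vector(v_prime)

  d0 <- as.vector(retardation_from_circular(vp))
  g0 <- 0.5 * atan2(-qp, up)
  best_d <- d0; best_g <- g0
  best_cost <- biref_cost(d0, g0, q, u, v, qp, up, vp)
  iters <- 0L
  for (off in c(0, pi / 4, pi / 2, 3 * pi / 4)) {
    d <- d0; g <- g0 + off
    lambda <- rep(1e-8, length(d))
    cost <- biref_cost(d, g, q, u, v, qp, up, vp)
    for (it in seq_len(max_iter)) {
      r <- biref_residuals(d, g, q, u, v, qp, up, vp)
      J <- biref_jacobian(d, g, q, u, v)
      a <- J$d1d^2 + J$d2d^2 + J$d3d^2 + lambda
      b <- J$d1d * J$d1g + J$d2d * J$d2g + J$d3d * J$d3g
      cc <- J$d1g^2 + J$d2g^2 + J$d3g^2 + lambda
      g1 <- J$d1d * r$r1 + J$d2d * r$r2 + J$d3d * r$r3
      g2 <- J$d1g * r$r1 + J$d2g * r$r2 + J$d3g * r$r3
      det <- a * cc - b^2
      det[det == 0] <- .Machine$double.eps
      sd_ <- -(cc * g1 - b * g2) / det
      sg_ <- -(-b * g1 + a * g2) / det
      nd <- pmin(pmax(d + sd_, 0), pi)
      ng <- g + sg_
      ncost <- biref_cost(nd, ng, q, u, v, qp, up, vp)
      improved <- ncost <= cost
      d[improved] <- nd[improved]
      g[improved] <- ng[improved]
      cost[improved] <- ncost[improved]
      lambda[improved] <- pmax(lambda[improved] / 4, 1e-12)
      lambda[!improved] <- lambda[!improved] * 10
      iters <- it
      if (max(abs(sd_[improved]), abs(sg_[improved]), 0) < tol &&
          all(lambda[!improved] > 1e6)) break
      if (all(!improved) && min(lambda) > 1e8) break
      if (max(abs(c(sd_, sg_))) < tol) break
    }
    better <- cost < best_cost
    best_d[better] <- d[better]
    best_g[better] <- g[better]
    best_cost[better] <- cost[better]
  }
  converged <- best_cost < 1e-16 + 1e-10 * (qp^2 + up^2 + vp^2)
  ## non-converged pixels fall back to the circular-approximation estimate
  best_d[!converged] <- d0[!converged]
  best_g[!converged] <- g0[!converged]
  gamma <- best_g %% pi
  gamma[best_d < tol_delta] <- NA_real_
  out <- list(delta = best_d, gamma = gamma, converged = converged,
              iterations = iters, cost = best_cost)
  if (!is.null(shp)) {
    dim(out$delta) <- shp; dim(out$gamma) <- shp
    dim(out$converged) <- shp; dim(out$cost) <- shp
  }
  structure(out, class = "biref_inversion")
}

#' @export
print.biref_inversion <- function(x, ...) {
  cat(sprintf("Birefringence inversion: %d pixels, %d not converged\n",
              length(x$delta), sum(!x$converged)))
  cat(sprintf("  delta in [%.4g, %.4g] rad; max residual cost %.3g\n",
              min(x$delta), max(x$delta), max(x$cost)))
  invisible(x)
}

#' Retardation and optic-axis maps from sample and reference Stokes images
#'
#' Full measurement chain: normalises the with-sample Stokes image (and the
#' without-sample reference), then inverts the sample model. In
#' `"circular"` mode the circular-illumination shortcut is applied
#' (`delta = acos(v')`, axis from the linear components) regardless of the
#' true input — exact for circular input, biased for elliptical input. In
#' `"full"` mode the three-equation least-squares inversion against the
#' measured input state is used.
#'
#' @param img with-sample [stokes_image()].
#' @param input input polarisation: a [polarisation_state()], length-4
#'   Stokes vector, or a reference `stokes_image` measured without the
#'   sample (its spatial median normalised state is used). Required for
#'   `"full"` mode; optional for `"circular"`.
#' @param mode `"circular"` or `"full"`.
#' @param eps_ip passed to [normalise_stokes()].
#' @return List of class `"retardation_map"`: `delta`, `gamma`, `mode`,
#'   `diagnostics` (clamp and convergence counts), `pixel_size_um`.
#' @export
retardation_map <- function(img, input = NULL,
                            mode = c("circular", "full"), eps_ip = NULL) {
  mode <- match.arg(mode)
  ns <- normalise_stokes(img, eps_ip)
  diagnostics <- list(n_masked = ns$n_masked)
  if (mode == "circular") {
    delta <- retardation_from_circular(ns$v)
    diagnostics$n_clamped <- attr(delta, "n_clamped")
    gamma <- axis_from_linear(ns$q, ns$u)
  } else {
    if (is.null(input)) stop("'full' mode requires the input state")
    st <- input_state_quv(input)
    inv <- retardation_full_inversion(ns$q, ns$u, ns$v, st)
    delta <- inv$delta; gamma <- inv$gamma
    diagnostics$n_not_converged <- sum(!inv$converged, na.rm = TRUE)
  }
  structure(list(delta = delta, gamma = gamma, mode = mode,
                 diagnostics = diagnostics,
                 pixel_size_um = img$pixel_size_um),
            class = "retardation_map")
}

## normalised (q,u,v) of an input specification: Stokes vector or reference
## stokes_image (spatial median of its normalised components)
input_state_quv <- function(input) {
  if (inherits(input, "stokes_image")) {
    ns <- normalise_stokes(input)
    st <- c(stats::median(ns$q, na.rm = TRUE),
            stats::median(ns$u, na.rm = TRUE),
            stats::median(ns$v, na.rm = TRUE))
  } else {
    s <- unclass(input)
    if (length(s) == 4) {
      ip <- sqrt(sum(s[2:4]^2))
      if (ip <= 0) stop("input state has no polarised part")
      st <- s[2:4] / ip
    } else if (length(s) == 3) st <- s
    else stop("input must be a Stokes vector, (q,u,v), or a stokes_image")
  }
  st / sqrt(sum(st^2))
}

#' @export
print.retardation_map <- function(x, ...) {
  cat(sprintf("Retardation map (%s mode): %d x %d pixels\n",
              x$mode, nrow(as.matrix(x$delta)), ncol(as.matrix(x$delta))))
  cat(sprintf("  delta in [%.4g, %.4g] rad\n", min(x$delta, na.rm = TRUE),
              max(x$delta, na.rm = TRUE)))
  invisible(x)
}

#' Error profile of the circular-illumination estimator for elliptical input
#'
#' For illumination with ellipticity angle below the ideal 45 degrees, the
#' shortcut `delta = acos(v')` is biased, with an error depending on the
#' input azimuth and the sample orientation. This sweeps the sample
#' optic-axis angle over a grid at fixed true retardation and reports the
#' signed estimator error, comparing against the exact forward model.
#'
#' @param delta_s true retardation (rad).
#' @param ellipticity input ellipticity angle (rad), in `(0, pi/4]`;
#'   `pi/4` is perfect circular light (zero error).
#' @param gammas optic-axis grid (rad); default 181 points over `[0, pi)`.
#' @param azimuth input polarisation azimuth (rad).
#' @return data.frame of class `"circular_error_profile"` with columns
#'   `gamma`, `delta_hat`, `error`; attributes `max_abs_error`,
#'   `mean_abs_error`, `delta_s`, `ellipticity`.
#' @export
circular_input_error_profile <- function(delta_s, ellipticity,
                                         gammas = seq(0, pi, length.out = 181)[-181],
                                         azimuth = 0) {
  if (!(ellipticity > 0 && ellipticity <= pi / 4 + 1e-12))
    stop("ellipticity must lie in (0, pi/4]")
  st <- elliptical_state(ellipticity, azimuth)
  quv <- input_state_quv(st)
  out <- propagate(list(q = quv[1], u = quv[2], v = quv[3]),
                   sample_map(matrix(rep(delta_s, length(gammas))),
                              matrix(gammas), 1))
  dh <- as.vector(retardation_from_circular(out$v))
  err <- dh - delta_s
  structure(data.frame(gamma = gammas, delta_hat = dh, error = err),
            class = c("circular_error_profile", "data.frame"),
            max_abs_error = max(abs(err)), mean_abs_error = mean(abs(err)),
            delta_s = delta_s, ellipticity = ellipticity)
}

#' Background (baseline) correction of a retardation map
#'
#' Estimates the non-specific baseline retardation from a user-supplied
#' no-tissue region (default) or as the modal value of the map, and
#' subtracts it. Negative corrected values are retained: they indicate
#' regions whose optic axis is rotated by 90 degrees relative to the
#' polarimeter x-axis.
#'
#' @param map retardation matrix (rad).
#' @param region no-tissue region as `c(x, y, w, h)` in pixel coordinates
#'   (1-based column/row of the top-left corner); required for
#'   `method = "region"`.
#' @param method `"region"` (mean over the region) or `"mode"` (modal value
#'   via a kernel density estimate).
#' @return List with `corrected` (matrix), `baseline` (scalar), `method`.
#' @export
background_correct <- function(map, region = NULL,
                               method = c("region", "mode")) {
  method <- match.arg(method)
  map <- as.matrix(map)
  if (method == "region") {
    if (is.null(region) || length(region) != 4)
      stop("method 'region' requires region = c(x, y, w, h)")
    x <- region[1]; y <- region[2]; w <- region[3]; h <- region[4]
    if (x < 1 || y < 1 || x + w - 1 > ncol(map) || y + h - 1 > nrow(map))
      stop("background region lies outside the map")
    vals <- map[y:(y + h - 1), x:(x + w - 1)]
    vals <- vals[is.finite(vals)]
    if (length(vals) == 0) stop("background region is empty (all masked)")
    baseline <- mean(vals)
  } else {
    vals <- map[is.finite(map)]
    if (length(vals) == 0) stop("map has no finite values")
    if (stats::sd(vals) == 0) baseline <- vals[1]
    else {
      dd <- stats::density(vals, n = 2048)
      baseline <- dd$x[which.max(dd$y)]
    }
  }
  list(corrected = map - baseline, baseline = baseline, method = method)
}
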