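## Depolarisation <-> sigma conversions (sigma = 1/P, Dp = sqrt(1 - P^2))
sigma_from_dp <- function(dp) 1 / sqrt(1 - dp^2)
dp_from_sigma <- function(sigma) sqrt(1 - 1 / sigma^2)

#' Specification of a synthetic tissue phantom
#'
#' Describes a procedurally generated birefringence phantom with known ground
#' truth. The geometry emulates the collagen organisation of the tissue types
#' this pipeline is aimed at: concentric perivascular rings
#' (`"placenta_villi"`), oriented fibre bands (`"dermis"`), a dense, high
#' retardation, strongly depolarising lesion with chaotic fibre orientation
#' over a dermis-like background (`"keloid"`), and a uniform field
#' (`"flat"`). Magnitude defaults are anchored to representative tissue
#' values: peak retardation 0.04 rad (placental perivascular collagen),
#' 1.00 rad (normal dermis), 1.40 rad (keloid); tissue depolarisation 0.37,
#' substrate 0.44 (mid-range of the typical 0.40-0.48 background band),
#' keloid maximum 0.96.
#'
#' @param kind one of `"placenta_villi"`, `"dermis"`, `"keloid"`, `"flat"`.
#' @param shape image size in pixels, `c(nrow, ncol)`.
#' @param seed integer seed; identical seeds give bit-identical phantoms.
#' @param delta_peak peak tissue retardation (rad); kind-specific default.
#' @param delta_baseline additive substrate baseline retardation (rad);
#'   default 0 so phantom retardation is tissue-only. Set to e.g. 0.11 rad
#'   to emulate a residual instrument/substrate baseline.
#' @param dp_tissue,dp_substrate,dp_max depolarisation of tissue, substrate
#'   and (keloid) lesion core.
#' @param n_villi number of villus rings (placenta kind).
#' @param band_period fibre band period in pixels (dermis/keloid kinds).
#' @param orientation_jitter SD (rad) of the optic-axis perturbation field.
#' @param lesion_fraction approximate lesion diameter as a fraction of the
#'   image (keloid kind).
#' @param delta_flat,gamma_flat,sigma_flat constants for the flat kind.
#' @return An object of class `"phantom_spec"`.
#' @export
phantom_spec <- function(kind = c("placenta_villi", "dermis", "keloid", "flat"),
                         shape = c(256L, 256L), seed = 1L,
                         delta_peak = NULL, delta_baseline = 0,
                         dp_tissue = 0.37, dp_substrate = 0.44, dp_max = 0.96,
                         n_villi = 6L, band_period = 24,
                         orientation_jitter = 0.08, lesion_fraction = 0.45,
                         delta_flat = 0, gamma_flat = 0, sigma_flat = 1) {
  kind <- match.arg(kind)
  if (is.null(delta_peak))
    delta_peak <- switch(kind, placenta_villi = 0.04, dermis = 1.00,
                         keloid = 1.40, flat = delta_flat)
  stopifnot(length(shape) == 2, all(shape >= 8) || kind == "flat")
  if (delta_peak < 0 || delta_peak + delta_baseline > pi)
    stop("delta_peak + delta_baseline must lie in [0, pi]")
  if (any(c(dp_tissue, dp_substrate, dp_max) < 0) ||
      any(c(dp_tissue, dp_substrate, dp_max) >= 1))
    stop("depolarisation values must lie in [0, 1)")
  structure(list(kind = kind, shape = as.integer(shape), seed = as.integer(seed),
                 delta_peak = delta_peak, delta_baseline = delta_baseline,
                 dp_tissue = dp_tissue, dp_substrate = dp_substrate,
                 dp_max = dp_max, n_villi = as.integer(n_villi),
                 band_period = band_period,
                 orientation_jitter = orientation_jitter,
                 lesion_fraction = lesion_fraction,
                 delta_flat = delta_flat, gamma_flat = gamma_flat,
                 sigma_flat = sigma_flat),
            class = "phantom_spec")
}

#' Acquisition noise model
#'
#' Stand-in camera noise model for rendered acquisitions: additive Gaussian
#' read noise on every demodulated signal plane, plus optional shot (Poisson)
#' noise on the DC plane at `photon_scale` counts per unit intensity.
#'
#' @param read_noise_sd Gaussian SD in signal units (>= 0).
#' @param photon_scale counts per unit intensity for the Poisson component;
#'   `NULL` disables shot noise.
#' @param seed integer seed for the noise draws.
#' @return An object of class `"noise_spec"`.
#' @export
noise_spec <- function(read_noise_sd = 0, photon_scale = NULL, seed = 1L) {
  stopifnot(read_noise_sd >= 0)
  if (!is.null(photon_scale) && photon_scale <= 0)
    stop("photon_scale must be positive or NULL")
  structure(list(read_noise_sd = read_noise_sd, photon_scale = photon_scale,
                 seed = as.integer(seed)),
            class = "noise_spec")
}

with_seed <- function(seed, expr) {
  old <- get0(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

## simple separable box blur, used to make smooth random fields
box_blur <- function(m, passes = 2L) {
  for (i in seq_len(passes)) {
    m <- (m + rbind(m[1, , drop = FALSE], m[-nrow(m), , drop = FALSE]) +
            rbind(m[-1, , drop = FALSE], m[nrow(m), , drop = FALSE])) / 3
    m <- (m + cbind(m[, 1, drop = FALSE], m[, -ncol(m), drop = FALSE]) +
            cbind(m[, -1, drop = FALSE], m[, ncol(m), drop = FALSE])) / 3
  }
  m
}

#' Generate a synthetic tissue phantom
#'
#' Builds the per-pixel ground-truth fields (retardation `delta`, optic-axis
#' angle `gamma`, depolarisation factor `sigma`) for the geometry described
#' by the spec. Retardation fields are rescaled so the maximum equals
#' `delta_peak` (plus any baseline) by construction. Deterministic per seed.
#'
#' @param spec a [phantom_spec()].
#' @return List of class `"phantom"`: `map` (a [sample_map()]), `truth`
#'   (delta, gamma, sigma plus the logical `tissue` mask), and `spec`.
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  ny <- spec$shape[1]; nx <- spec$shape[2]
  row <- matrix(seq_len(ny), ny, nx)
  col <- matrix(seq_len(nx), ny, nx, byrow = TRUE)
  res <- with_seed(spec$seed, {
    switch(spec$kind,
      flat = {
        list(delta = matrix(spec$delta_flat, ny, nx),
             gamma = matrix(spec$gamma_flat, ny, nx),
             sigma = matrix(spec$sigma_flat, ny, nx),
             tissue = matrix(spec$delta_flat > 0, ny, nx))
      },
      placenta_villi = {
        rel <- matrix(0, ny, nx)
        ang <- matrix(0, ny, nx)
        rmin <- 0.06 * min(ny, nx); rmax <- 0.16 * min(ny, nx)
        for (k in seq_len(spec$n_villi)) {
          cy <- stats::runif(1, 0.15, 0.85) * ny
          cx <- stats::runif(1, 0.15, 0.85) * nx
          r0 <- stats::runif(1, rmin, rmax)
          w <- 0.25 * r0
          d <- sqrt((row - cy)^2 + (col - cx)^2)
          contrib <- exp(-((d - r0) / w)^2 / 2)
          upd <- contrib > rel
          ## optic axis tangential to the ring (collagen wrapping the vessel)
          ang[upd] <- (atan2(row - cy, col - cx)[upd] + pi / 2) %% pi
          rel <- pmax(rel, contrib)
        }
        rel <- rel / max(rel)
        list(delta = spec$delta_baseline + spec$delta_peak * rel,
             gamma = ang,
             sigma = ifelse(rel > 0.05, sigma_from_dp(spec$dp_tissue),
                            sigma_from_dp(spec$dp_substrate)),
             tissue = rel > 0.05)
      },
      dermis = {
        phi1 <- stats::runif(1, 0, pi)
        phi2 <- (phi1 + stats::runif(1, pi / 3, 2 * pi / 3)) %% pi
        p1 <- col * cos(phi1) + row * sin(phi1)
        p2 <- col * cos(phi2) + row * sin(phi2)
        b1 <- sin(pi * p1 / spec$band_period)^2
        b2 <- 0.8 * sin(pi * p2 / spec$band_period + 1)^2
        rel <- pmax(b1, b2); rel <- rel / max(rel)
        jitter <- box_blur(matrix(stats::rnorm(ny * nx,
                                               sd = spec$orientation_jitter),
                                  ny, nx), 3L)
        ang <- (ifelse(b1 >= b2, phi1, phi2) + jitter) %% pi
        list(delta = spec$delta_baseline + spec$delta_peak * rel,
             gamma = ang,
             sigma = ifelse(rel > 0.05, sigma_from_dp(spec$dp_tissue),
                            sigma_from_dp(spec$dp_substrate)),
             tissue = rel > 0.05)
      },
      keloid = {
        bg <- generate_phantom(phantom_spec("dermis", spec$shape,
                                            seed = spec$seed + 1L,
                                            delta_peak = 1.00,
                                            delta_baseline = spec$delta_baseline,
                                            dp_tissue = spec$dp_tissue,
                                            dp_substrate = spec$dp_substrate,
                                            band_period = spec$band_period))
        cy <- ny * stats::runif(1, 0.4, 0.6)
        cx <- nx * stats::runif(1, 0.4, 0.6)
        ax <- spec$lesion_fraction * nx / 2
        ay <- spec$lesion_fraction * ny / 2 * stats::runif(1, 0.7, 1)
        r2 <- ((col - cx) / ax)^2 + ((row - cy) / ay)^2
        taper <- pmax(0, 1 - r2)            # 1 at centre, 0 at rim
        taper <- taper / max(taper)
        lesion <- taper > 0
        delta <- bg$truth$delta
        ## lesion: dense disorganised collagen at high retardation
        delta[lesion] <- pmax(delta[lesion],
                              spec$delta_baseline +
                                spec$delta_peak * sqrt(taper[lesion]))
        chaotic <- box_blur(matrix(stats::runif(ny * nx, 0, pi), ny, nx), 2L)
        gamma <- bg$truth$gamma
        gamma[lesion] <- chaotic[lesion] %% pi
        dp <- dp_from_sigma(bg$truth$sigma)
        dp[lesion] <- spec$dp_tissue +
          (spec$dp_max - spec$dp_tissue) * taper[lesion]
        list(delta = delta, gamma = gamma, sigma = sigma_from_dp(dp),
             tissue = bg$truth$tissue | lesion)
      })
  })
  map <- sample_map(res$delta, res$gamma, res$sigma)
  structure(list(map = map,
                 truth = list(delta = res$delta, gamma = res$gamma,
                              sigma = res$sigma, tissue = res$tissue),
                 spec = spec),
            class = "phantom")
}

#' @export
print.phantom <- function(x, ...) {
  cat(sprintf("Phantom '%s': %d x %d pixels (seed %d)\n", x$spec$kind,
              x$spec$shape[1], x$spec$shape[2], x$spec$seed))
  cat(sprintf("  delta in [%.4g, %.4g] rad; Dp up to %.3g; %.1f%% tissue\n",
              min(x$truth$delta), max(x$truth$delta),
              max(dp_from_sigma(x$truth$sigma)),
              100 * mean(x$truth$tissue)))
  invisible(x)
}

#' Render a noisy acquisition of a sample map through the instrument
#'
#' Full forward chain: per pixel, the sample Mueller model transforms the
#' input Stokes state; the instrument response ([signal_matrix()]) converts
#' the transmitted Stokes parameters to the four demodulated signal planes;
#' optional noise is added. The no-sample reference acquisition (the input
#' state seen directly) is rendered alongside, emulating measurements taken
#' with and without the sample.
#'
#' @param map a [sample_map()] (or the `map` of a [generate_phantom()]).
#' @param input input Stokes state (length-4 vector or
#'   [polarisation_state()]); default perfect right-circular `(1, 0, 0, 1)`.
#' @param cfg a [polarimeter_config()].
#' @param noise a [noise_spec()] or `NULL` for a noiseless render.
#' @return List of class `"acquisition"`: `signals` and `reference`
#'   ([harmonic_signals()] stacks), `stokes_truth` (noiseless transmitted
#'   [stokes_image()]), `input`, `cfg`, `noise`.
#' @export
render_acquisition <- function(map, input = c(1, 0, 0, 1),
                               cfg = polarimeter_config(), noise = NULL) {
  if (inherits(map, "phantom")) map <- map$map
  stopifnot(inherits(map, "sample_map"))
  s <- unclass(input)
  stopifnot(length(s) == 4)
  ## absolute transmitted Stokes parameters per pixel (Mueller model rows)
  out <- propagate(list(i = s[1], q = s[2], u = s[3], v = s[4]), map)
  A <- signal_matrix(cfg)
  shp <- dim(map$delta)
  to_planes <- function(stokes4) {
    sig <- A %*% stokes4
    lapply(1:4, function(i) { v <- sig[i, ]; dim(v) <- shp; v })
  }
  planes <- to_planes(rbind(as.vector(out$i), as.vector(out$q),
                            as.vector(out$u), as.vector(out$v)))
  ref_sig <- as.vector(A %*% s)
  ref_planes <- lapply(ref_sig, function(v) matrix(v, shp[1], shp[2]))
  if (!is.null(noise)) {
    stopifnot(inherits(noise, "noise_spec"))
    add_noise <- function(pl) {
      if (!is.null(noise$photon_scale)) {
        lam <- pmax(pl[[1]], 0) * noise$photon_scale
        pl[[1]] <- stats::rpois(length(lam), lam) / noise$photon_scale
        dim(pl[[1]]) <- shp
      }
      if (noise$read_noise_sd > 0)
        pl <- lapply(pl, function(p)
          p + matrix(stats::rnorm(length(p), 0, noise$read_noise_sd),
                     shp[1], shp[2]))
      pl
    }
    noisy <- with_seed(noise$seed, list(sig = add_noise(planes),
                                        ref = add_noise(ref_planes)))
    planes <- noisy$sig
    ref_planes <- noisy$ref
  }
  structure(list(
    signals = harmonic_signals(planes[[1]], planes[[2]], planes[[3]], planes[[4]]),
    reference = harmonic_signals(ref_planes[[1]], ref_planes[[2]],
                                 ref_planes[[3]], ref_planes[[4]]),
    stokes_truth = stokes_image(matrix(out$i, shp[1], shp[2]),
                                matrix(out$q, shp[1], shp[2]),
                                matrix(out$u, shp[1], shp[2]),
                                matrix(out$v, shp[1], shp[2])),
    input = s, cfg = cfg, noise = noise),
    class = "acquisition")
}

#' Reconstruct a Stokes image from a signal stack
#'
#' @param signals a [harmonic_signals()] stack (matrix planes).
#' @param K a [k_matrix()] or `"k_calibration"` fit.
#' @param pixel_size_um,magnification spatial metadata for the result.
#' @return A [stokes_image()].
#' @export
reconstruct_stokes <- function(signals, K, pixel_size_um = 1 / 6.17,
                               magnification = "40x") {
  if (inherits(K, "k_calibration")) K <- K$kmat
  st <- stokes_from_signals(signals, K)
  stokes_image(st$I, st$Q, st$U, st$V, pixel_size_um, magnification)
}

#' Read-noise level that produces a target retardation noise floor
#'
#' First-order noise propagation through the reconstruction chain: computes
#' the numerical gradient of the circular-mode retardation estimate with
#' respect to the four demodulated signals at the given operating point
#' (background retardation, input state, calibration matrix), and returns
#' the per-signal Gaussian SD for which the retardation SD equals
#' `target_sd`. The operating point must have nonzero retardation: at
#' `delta = 0` the arccos relation is degenerate and no Gaussian signal
#' noise maps linearly to a retardation SD.
#'
#' @param target_sd desired retardation noise SD (rad), e.g. 0.005.
#' @param delta_bg background operating retardation (rad), e.g. 0.11.
#' @param input input Stokes state.
#' @param cfg a [polarimeter_config()].
#' @param K calibration matrix; default [true_k_matrix()] of `cfg`.
#' @return Scalar read-noise SD in signal units.
#' @export
read_noise_for_retardation_sd <- function(target_sd, delta_bg = 0.11,
                                          input = c(1, 0, 0, 1),
                                          cfg = polarimeter_config(),
                                          K = NULL) {
  stopifnot(target_sd > 0)
  if (delta_bg <= 1e-6)
    stop("operating-point retardation must be positive (arccos is degenerate at 0)")
  if (is.null(K)) K <- true_k_matrix(cfg)
  map1 <- sample_map(matrix(delta_bg), matrix(0), 1)
  acq <- render_acquisition(map1, input, cfg)
  s0 <- signal_vector(acq$signals)
  delta_of <- function(sig) {
    st <- as.matrix(K) %*% sig
    ip <- sqrt(sum(st[2:4]^2))
    acos(max(-1, min(1, st[4] / ip)))
  }
  h <- 1e-6 * max(abs(s0))
  grad <- vapply(1:4, function(i) {
    e <- numeric(4); e[i] <- h
    (delta_of(s0 + e) - delta_of(s0 - e)) / (2 * h)
  }, numeric(1))
  target_sd / sqrt(sum(grad^2))
}
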