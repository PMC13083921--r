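## Positions of the structural zeros in the calibration matrix pattern
## (row, col), with the eight free elements k1..k8 at:
##   [k1 k2 k3 0 ; 0 k4 k5 0 ; 0 k6 k7 0 ; 0 0 0 k8]
k_zero_positions <- cbind(row = c(1, 2, 2, 3, 3, 4, 4, 4),
                          col = c(4, 1, 4, 1, 4, 1, 2, 3))
k_free_positions <- cbind(row = c(1, 1, 1, 2, 2, 3, 3, 4),
                          col = c(1, 2, 3, 2, 3, 2, 3, 4))

#' Sparse calibration matrix K linking harmonic signals to Stokes parameters
#'
#' The 4x4 transformation `(I, Q, U, V) = K (S_DC, S_QU1, S_QU2, S_v)` has
#' eight free elements k1..k8 arranged as
#' \preformatted{
#'   [ k1 k2 k3 0  ]
#'   [ 0  k4 k5 0  ]
#'   [ 0  k6 k7 0  ]
#'   [ 0  0  0  k8 ]
#' }
#' This sparsity pattern is a necessary condition for K to exist for the
#' dual-PEM instrument. Invariants enforced: k1 != 0, k8 != 0, and the 2x2
#' linear block `[k4 k5; k6 k7]` invertible.
#'
#' @param k1,k2,k3,k4,k5,k6,k7,k8 the eight elements.
#' @return An object of class `"k_matrix"`.
#' @export
k_matrix <- function(k1, k2 = 0, k3 = 0, k4, k5 = 0, k6 = 0, k7, k8) {
  k <- c(k1 = k1, k2 = k2, k3 = k3, k4 = k4, k5 = k5, k6 = k6, k7 = k7, k8 = k8)
  if (k[["k1"]] == 0) stop("k1 must be nonzero")
  if (k[["k8"]] == 0) stop("k8 must be nonzero")
  blk <- matrix(k[c("k4", "k5", "k6", "k7")], 2, 2, byrow = TRUE)
  if (abs(det(blk)) < .Machine$double.eps * max(abs(blk), 1))
    stop("the (k4, k5; k6, k7) block must be invertible")
  structure(list(k = k), class = "k_matrix")
}

#' @export
as.matrix.k_matrix <- function(x, ...) {
  M <- matrix(0, 4, 4)
  M[k_free_positions] <- x$k
  dimnames(M) <- list(c("I", "Q", "U", "V"),
                      c("S_DC", "S_QU1", "S_QU2", "S_v"))
  M
}

#' @export
print.k_matrix <- function(x, ...) {
  cat("Calibration matrix K (Stokes <- harmonic signals):\n")
  print(round(as.matrix(x), 10))
  invisible(x)
}

#' Build a k_matrix from a full 4x4 matrix
#'
#' Validates that the matrix respects the structural sparsity pattern within
#' `tol` (relative to the largest free element) and extracts k1..k8.
#'
#' @param M 4x4 numeric matrix.
#' @param tol relative tolerance for the zero positions.
#' @return A [k_matrix()].
#' @export
k_from_matrix <- function(M, tol = 1e-8) {
  stopifnot(is.matrix(M), all(dim(M) == 4))
  scale <- max(abs(M[k_free_positions]))
  if (any(abs(M[k_zero_positions]) > tol * scale))
    stop("matrix violates the calibration sparsity pattern")
  k <- M[k_free_positions]
  k_matrix(k[1], k[2], k[3], k[4], k[5], k[6], k[7], k[8])
}

#' Ground-truth calibration matrix of a simulated instrument
#'
#' Inverts the signal response matrix of [signal_matrix()], giving the K that
#' exactly recovers Stokes parameters from noiseless simulated signals.
#'
#' @param cfg a [polarimeter_config()].
#' @param tol relative tolerance for validating the sparsity pattern.
#' @return A [k_matrix()].
#' @export
true_k_matrix <- function(cfg, tol = 1e-8) {
  k_from_matrix(solve(signal_matrix(cfg)), tol = tol)
}

#' Recover Stokes parameters from harmonic signals
#'
#' Applies `(I, Q, U, V) = K (S_DC, S_QU1, S_QU2, S_v)` per pixel; signal
#' planes may be scalars, vectors or matrices of one common shape.
#'
#' @param signals a [harmonic_signals()] object.
#' @param K a [k_matrix()].
#' @return For scalar signals a [polarisation_state()]; otherwise a list of
#'   planes `I`, `Q`, `U`, `V` with the input shape.
#' @export
stokes_from_signals <- function(signals, K) {
  stopifnot(inherits(signals, "harmonic_signals"), inherits(K, "k_matrix"))
  M <- as.matrix(K)
  dm <- dim(signals$S_DC)
  S <- unname(M) %*% rbind(as.vector(signals$S_DC), as.vector(signals$S_QU1),
                           as.vector(signals$S_QU2), as.vector(signals$S_v))
  if (is.null(dm) && length(signals$S_DC) == 1L) {
    ## reconstructed states may be marginally unphysical under noise;
    ## no warning here, downstream clamping handles it
    return(structure(c(I = S[1, 1], Q = S[2, 1], U = S[3, 1], V = S[4, 1]),
                     class = "polarisation_state"))
  }
  reshape <- function(v) { dim(v) <- dm; v }
  list(I = reshape(S[1, ]), Q = reshape(S[2, ]),
       U = reshape(S[3, ]), V = reshape(S[4, ]))
}

#' Simulate a calibration measurement set
#'
#' Generates the harmonic signals the instrument would measure for a set of
#' known polarisation-state-generator states, optionally with additive
#' Gaussian signal noise — the in-silico analogue of recording calibration
#' frames with a polarisation state generator.
#'
#' @param states numeric n x 4 matrix of known Stokes rows (I, Q, U, V).
#' @param cfg a [polarimeter_config()].
#' @param noise_sd Gaussian noise SD added to every signal (signal units).
#' @param seed optional integer seed for the noise draws.
#' @return data.frame with columns state_I..state_V, S_DC, S_QU1, S_QU2, S_v.
#' @export
simulate_calibration_set <- function(states, cfg, noise_sd = 0, seed = NULL) {
  states <- as.matrix(states)
  stopifnot(ncol(states) == 4)
  A <- signal_matrix(cfg)
  sig <- states %*% t(A)
  if (noise_sd > 0) {
    if (!is.null(seed)) {
      old <- get0(".Random.seed", globalenv())
      on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
      set.seed(seed)
    }
    sig <- sig + matrix(stats::rnorm(length(sig), 0, noise_sd), nrow(sig))
  }
  out <- data.frame(states, sig)
  names(out) <- c("state_I", "state_Q", "state_U", "state_V",
                  "S_DC", "S_QU1", "S_QU2", "S_v")
  out
}

#' Canonical polarisation-state-generator states
#'
#' The six Poincare-axis states: horizontal, vertical, +45, -45 linear, and
#' right/left circular, all at unit intensity.
#'
#' @return A 6 x 4 matrix of Stokes rows.
#' @export
canonical_states <- function() {
  m <- rbind(H    = c(1,  1,  0,  0),
             V    = c(1, -1,  0,  0),
             P45  = c(1,  0,  1,  0),
             M45  = c(1,  0, -1,  0),
             RCP  = c(1,  0,  0,  1),
             LCP  = c(1,  0,  0, -1))
  colnames(m) <- c("I", "Q", "U", "V")
  m
}

cal_as_matrices <- function(cal) {
  need <- c("state_I", "state_Q", "state_U", "state_V",
            "S_DC", "S_QU1", "S_QU2", "S_v")
  if (!all(need %in% names(cal)))
    stop("calibration set must have columns ", paste(need, collapse = ", "))
  list(states = as.matrix(cal[, need[1:4]]),
       signals = as.matrix(cal[, need[5:8]]))
}

## Row-wise linear least-squares fit respecting the sparsity pattern, with
## identifiability diagnostics. Each Stokes row of Eq (I,Q,U,V) = K s is an
## independent regression on a subset of signal columns.
fit_k_linear <- function(states, signals) {
  rows <- list(
    list(y = 1, cols = 1:3, ks = c("k1", "k2", "k3")),
    list(y = 2, cols = 2:3, ks = c("k4", "k5")),
    list(y = 3, cols = 2:3, ks = c("k6", "k7")),
    list(y = 4, cols = 4,   ks = "k8"))
  k <- stats::setNames(numeric(8), paste0("k", 1:8))
  cond <- numeric(4)
  fitted <- matrix(0, nrow(states), 4)
  for (r in rows) {
    X <- signals[, r$cols, drop = FALSE]
    qrX <- qr(X)
    if (qrX$rank < ncol(X)) {
      bad <- r$ks[qrX$pivot[seq.int(qrX$rank + 1L, ncol(X))]]
      stop("calibration design is rank deficient: unidentifiable element(s) ",
           paste(bad, collapse = ", "),
           " (the supplied states do not excite them)")
    }
    beta <- qr.coef(qrX, states[, r$y])
    k[r$ks] <- beta
    fitted[, r$y] <- X %*% beta
    d <- svd(X, nu = 0, nv = 0)$d
    cond[r$y] <- d[1] / d[length(d)]
  }
  list(k = k, fitted = fitted, condition = cond)
}

## Nonlinear refinement: jointly fits k1..k8 and the generator-state
## parameters (azimuth, ellipticity of each nominally fully polarised state)
## by Levenberg-Marquardt, mirroring calibration procedures in which the
## state generator itself is imperfect.
fit_k_nonlinear <- function(states, signals, k_start) {
  n <- nrow(states)
  th0 <- 0.5 * atan2(states[, 3], states[, 2])
  ep0 <- 0.5 * asin(pmax(-1, pmin(1, states[, 4] /
    pmax(sqrt(rowSums(states[, 2:4]^2)), 1e-12))))
  par0 <- c(k_start, th0, ep0)
  resid_fun <- function(p) {
    k <- p[1:8]
    th <- p[8 + seq_len(n)]
    ep <- p[8 + n + seq_len(n)]
    M <- matrix(0, 4, 4); M[k_free_positions] <- k
    model <- cbind(1, cos(2 * ep) * cos(2 * th),
                   cos(2 * ep) * sin(2 * th), sin(2 * ep))
    as.vector(model - signals %*% t(M))
  }
  fit <- minpack.lm::nls.lm(par0, fn = resid_fun,
                            control = minpack.lm::nls.lm.control(
                              maxiter = 200, ftol = 1e-12, ptol = 1e-12))
  list(k = stats::setNames(fit$par[1:8], paste0("k", 1:8)),
       info = fit$info, deviance = fit$deviance)
}

#' Estimate the calibration matrix from known states and measured signals
#'
#' Fits the eight free elements of K by least squares on
#' `(I, Q, U, V) = K (S_DC, S_QU1, S_QU2, S_v)` over a set of
#' known-state / measured-signal pairs. The relation is linear in k1..k8, so
#' the default solver is exact row-wise linear least squares; the
#' `"nonlinear"` method additionally refines the generator-state azimuth and
#' ellipticity angles by Levenberg-Marquardt, for calibration sets in which
#' the nominal generator states are imperfect.
#'
#' @param cal a data.frame with columns `state_I..state_V` and
#'   `S_DC, S_QU1, S_QU2, S_v`, e.g. from [simulate_calibration_set()] or
#'   [read_calibration_csv()].
#' @param method `"linear"` (default) or `"nonlinear"`.
#' @return An object of class `"k_calibration"` with components `kmat` (a
#'   [k_matrix()]), `coefficients` (k1..k8), `residuals`, `fitted`, `rss`,
#'   `condition` (per-row design condition numbers), `n_states`, `method`.
#' @examples
#' cfg <- polarimeter_config()
#' cal <- simulate_calibration_set(canonical_states(), cfg)
#' fit <- calibrate(cal)
#' coef(fit)
#' @export
calibrate <- function(cal, method = c("linear", "nonlinear")) {
  method <- match.arg(method)
  m <- cal_as_matrices(cal)
  if (nrow(m$states) < 4)
    stop("at least 4 calibration states are required")
  lin <- fit_k_linear(m$states, m$signals)
  k <- lin$k
  extra <- NULL
  if (method == "nonlinear") {
    nl <- fit_k_nonlinear(m$states, m$signals, k)
    k <- nl$k
    extra <- nl[c("info", "deviance")]
  }
  M <- matrix(0, 4, 4); M[k_free_positions] <- k
  fitted <- m$signals %*% t(M)
  resid <- m$states - fitted
  structure(list(kmat = k_from_matrix(M, tol = Inf),
                 coefficients = k,
                 fitted = fitted,
                 residuals = resid,
                 rss = sum(resid^2),
                 condition = lin$condition,
                 n_states = nrow(m$states),
                 method = method,
                 nonlinear = extra,
                 call = match.call()),
            class = "k_calibration")
}

#' @export
coef.k_calibration <- function(object, ...) object$coefficients

#' @export
print.k_calibration <- function(x, ...) {
  cat(sprintf("Calibration fit (%s least squares, %d states)\n",
              x$method, x$n_states))
  print(round(x$coefficients, 8))
  cat(sprintf("Residual sum of squares: %.3g\n", x$rss))
  invisible(x)
}

#' @export
summary.k_calibration <- function(object, ...) {
  cat(sprintf("Calibration fit: %s least squares on %d states\n",
              object$method, object$n_states))
  print(object$kmat)
  cat(sprintf("RSS: %.3g; residual SD: %.3g\n", object$rss,
              stats::sd(object$residuals)))
  cat("Design condition numbers (I,Q,U,V rows):",
      sprintf("%.3g", object$condition), "\n")
  invisible(object)
}

#' @export
residuals.k_calibration <- function(object, ...) object$residuals

#' Predict Stokes parameters from harmonic signals with a calibration fit
#'
#' @param object a `"k_calibration"` fit.
#' @param signals a [harmonic_signals()] object (or a data.frame with signal
#'   columns, one row per measurement).
#' @param ... unused.
#' @return See [stokes_from_signals()].
#' @export
predict.k_calibration <- function(object, signals, ...) {
  if (is.data.frame(signals))
    signals <- harmonic_signals(signals$S_DC, signals$S_QU1,
                                signals$S_QU2, signals$S_v)
  stokes_from_signals(signals, object$kmat)
}

#' Check emergence of the calibration sparsity pattern
#'
#' Fits an *unconstrained* 4x4 matrix by least squares and reports the
#' largest magnitude found at the structural zero positions, relative to the
#' largest free element. For a well-aligned instrument the zeros emerge from
#' the data; a misaligned chain shows up as mass at the zero positions.
#'
#' @param cal calibration data.frame (as for [calibrate()]); at least 16
#'   states spanning the signal space.
#' @param tol relative tolerance defining a pass.
#' @return Class `"k_sparsity_report"`: `K_full` (the unconstrained fit),
#'   `max_zero_rel` (max relative magnitude at zero positions), `tol`,
#'   `pass`.
#' @export
validate_k_sparsity <- function(cal, tol = 1e-6) {
  m <- cal_as_matrices(cal)
  if (nrow(m$states) < 16)
    stop("at least 16 calibration states are required for the unconstrained fit")
  if (qr(m$signals)$rank < 4)
    stop("signals do not span four dimensions")
  ## states = signals %*% t(K): solve the multiresponse least squares
  Kt <- qr.coef(qr(m$signals), m$states)
  K <- t(Kt)
  scale <- max(abs(K[k_free_positions]))
  rel <- max(abs(K[k_zero_positions])) / scale
  structure(list(K_full = K, max_zero_rel = rel, tol = tol,
                 pass = rel < tol, n_states = nrow(m$states)),
            class = "k_sparsity_report")
}

#' @export
print.k_sparsity_report <- function(x, ...) {
  cat(sprintf("Unconstrained 4x4 fit over %d states\n", x$n_states))
  cat(sprintf("Max |element| at structural zeros: %.3g x max|k_i| (tol %.3g) -> %s\n",
              x$max_zero_rel, x$tol, if (x$pass) "PASS" else "EXCEEDS"))
  invisible(x)
}
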