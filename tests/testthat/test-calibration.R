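test_that("stokes_from_signals applies the sparse linear map", {
  K <- k_matrix(k1 = 1, k4 = 1, k7 = 1, k8 = 1)
  s <- harmonic_signals(2, 3, 4, 5)
  expect_equal(unclass(stokes_from_signals(s, K)),
               c(I = 2, Q = 3, U = 4, V = 5))
  z <- stokes_from_signals(harmonic_signals(0, 0, 0, 0), K)
  expect_equal(unname(unclass(z)), rep(0, 4))
  ## vectorised over pixel planes
  m <- matrix(1:6, 2, 3)
  pl <- stokes_from_signals(harmonic_signals(m, 2 * m, 3 * m, 4 * m), K)
  expect_equal(pl$U, 3 * m)
  expect_error(stokes_from_signals(harmonic_signals(m, 2, 3, 4), K))
})

test_that("k_matrix enforces its structural invariants", {
  expect_error(k_matrix(0, k4 = 1, k7 = 1, k8 = 1), "k1")
  expect_error(k_matrix(1, k4 = 1, k7 = 1, k8 = 0), "k8")
  expect_error(k_matrix(1, k4 = 1, k5 = 2, k6 = 2, k7 = 4, k8 = 1),
               "invertible")
  M <- matrix(1, 4, 4)
  expect_error(k_from_matrix(M), "sparsity")
})

test_that("calibration recovers the ground-truth matrix from noise-free data", {
  cfg <- default_cfg()
  K_true <- true_k_matrix(cfg)
  cal <- simulate_calibration_set(canonical_states(), cfg)
  fit <- calibrate(cal)
  scale <- max(abs(K_true$k))
  expect_lt(max(abs(coef(fit) - K_true$k)) / scale, 1e-8)
  ## forward-inverse identity on the states themselves
  rec <- predict(fit, cal)
  expect_equal(unname(rec$I), cal$state_I, tolerance = 1e-10)
  expect_equal(unname(rec$V), cal$state_V, tolerance = 1e-10)
})

test_that("noisy calibration recovers elements to better than 1 percent", {
  cfg <- default_cfg()
  K_true <- true_k_matrix(cfg)
  states <- random_states(50, seed = 3)
  cal <- simulate_calibration_set(states, cfg, noise_sd = 1e-3, seed = 42)
  fit <- calibrate(cal)
  rel <- abs(coef(fit) - K_true$k) / max(abs(K_true$k))
  expect_lt(max(rel), 0.01)
})

test_that("calibration error shrinks as the number of states grows", {
  cfg <- default_cfg()
  K_true <- true_k_matrix(cfg)
  err_at <- function(n, seed) {
    states <- rbind(canonical_states(),
                    if (n > 6) random_states(n - 6, seed = seed))
    cal <- simulate_calibration_set(states, cfg, noise_sd = 1e-3,
                                    seed = seed + 100)
    max(abs(coef(calibrate(cal)) - K_true$k)) / max(abs(K_true$k))
  }
  e6 <- mean(vapply(1:8, function(s) err_at(6, s), numeric(1)))
  e50 <- mean(vapply(1:8, function(s) err_at(50, s), numeric(1)))
  expect_lt(e50, e6)
})

test_that("degenerate calibration sets fail with informative messages", {
  cfg <- default_cfg()
  lin_only <- canonical_states()[1:4, ]  # V = 0 throughout
  cal <- simulate_calibration_set(lin_only, cfg)
  expect_error(calibrate(cal), "k8")
  expect_error(calibrate(simulate_calibration_set(canonical_states()[1:3, ], cfg)),
               "4 calibration states")
  same <- canonical_states()[c(1, 1, 1, 1, 1), ]
  expect_error(calibrate(simulate_calibration_set(same, cfg)),
               "unidentifiable")
})

test_that("nonlinear refinement agrees with the linear solution on exact data", {
  cfg <- default_cfg()
  cal <- simulate_calibration_set(canonical_states(), cfg)
  f_lin <- calibrate(cal, method = "linear")
  f_nl <- calibrate(cal, method = "nonlinear")
  expect_equal(coef(f_nl), coef(f_lin), tolerance = 1e-6)
})

test_that("the sparsity pattern emerges from an unconstrained fit", {
  cfg <- default_cfg()
  states <- rbind(canonical_states(), random_states(14, seed = 5))
  cal <- simulate_calibration_set(states, cfg)
  rep_ <- validate_k_sparsity(cal, tol = 1e-8)
  expect_true(rep_$pass)
  expect_lt(rep_$max_zero_rel, 1e-8)
  ## patterned and unconstrained fits coincide on exact data
  fit <- calibrate(cal)
  expect_lt(max(abs(rep_$K_full - as.matrix(fit$kmat))),
            1e-8 * max(abs(coef(fit))))
  expect_error(validate_k_sparsity(cal[1:10, ]), "16")
})

test_that("a perturbed signal chain breaks the sparsity pattern (informative report)", {
  ## emulate a residual static retardance before the analyser, which couples
  ## the circular component into a second-harmonic channel
  cfg <- default_cfg()
  states <- rbind(canonical_states(), random_states(14, seed = 6))
  A_bad <- signal_matrix(cfg)
  A_bad[3, 4] <- 0.05 * max(abs(A_bad))
  sig <- states %*% t(A_bad)
  cal <- data.frame(states, sig)
  names(cal) <- c("state_I", "state_Q", "state_U", "state_V",
                  "S_DC", "S_QU1", "S_QU2", "S_v")
  rep_ <- validate_k_sparsity(cal, tol = 1e-8)
  expect_false(rep_$pass)
  expect_gt(rep_$max_zero_rel, 1e-4)
})
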