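test_that("detector intensity handles degenerate chains correctly", {
  cfg <- default_cfg()
  t <- seq(0, 0.5, length.out = 101)
  ## unpolarised light is unaffected by the modulators
  expect_equal(detector_intensity(c(1, 0, 0, 0), cfg, t), rep(0.5, 101))
  ## static chain: aligned polariser transmits fully
  cfg0 <- polarimeter_config(beta = 0, A1 = 1e-12, A2 = 1e-12)
  expect_equal(detector_intensity(c(1, 1, 0, 0), cfg0, t), rep(1, 101),
               tolerance = 1e-9)
  expect_error(detector_intensity(c(1, 0, 0, 0), cfg, -1), "non-negative")
})

test_that("detector intensity is non-negative for physical input", {
  cfg <- default_cfg()
  t <- seq(0, 0.5, length.out = 2000)
  for (s in asplit(random_states(10, seed = 7), 1)) {
    expect_true(all(detector_intensity(s, cfg, t) >= -1e-12))
  }
})

test_that("modulation shifts polarisation information to the PEM harmonics", {
  cfg <- default_cfg()
  st <- c(1, 0.5, 0.5, 1) / sqrt(1.5)  # excites all demodulated lines
  st[1] <- 1
  ser <- simulate_intensity_series(st, cfg, n_samples = 8192)
  sp <- Mod(stats::fft(ser$x)) / length(ser$x)
  freq_index <- function(f) round(f * ser$period) + 1L  # bins of 1/T
  floor_level <- stats::median(sp)
  for (f in c(cfg$f1, 2 * cfg$f1, 2 * cfg$f2)) {
    expect_gt(sp[freq_index(f)], 1e3 * floor_level)
  }
  ## circular input modulates only through the f1 (circular) line
  ser_c <- simulate_intensity_series(c(1, 0, 0, 1), cfg, n_samples = 8192)
  sp_c <- Mod(stats::fft(ser_c$x)) / length(ser_c$x)
  expect_gt(sp_c[freq_index(cfg$f1)], 1e-3)
})

test_that("lock-in demodulation recovers amplitudes of synthetic tones", {
  cfg <- default_cfg()
  T0 <- 0.5
  t <- seq(0, T0, length.out = 4097)[1:4096]
  const <- list(t = t, x = rep(3.2, 4096))
  s <- lockin_demodulate(const, cfg)
  expect_equal(sig_vec(s), c(3.2, 0, 0, 0), tolerance = 1e-12)
  tone <- list(t = t, x = 3 + 2 * sin(2 * pi * cfg$f1 * t))
  s <- lockin_demodulate(tone, cfg)
  expect_equal(sig_vec(s), c(3, 0, 0, 2), tolerance = 1e-10)
})

test_that("lock-in rejects malformed series", {
  cfg <- default_cfg()
  t <- seq(0, 0.2, length.out = 4096)  # not a full common period
  expect_error(lockin_demodulate(list(t = t, x = rep(1, 4096)), cfg),
               "integer number")
  bad <- polarimeter_config(f1 = 50, f2 = 50 * sqrt(2))
  t2 <- seq(0, 1, length.out = 4096)
  expect_error(lockin_demodulate(list(t = t2, x = rep(1, 4096)), bad),
               "commensurate")
  t3 <- seq(0, 0.5, length.out = 513)[1:512]  # too sparse for 20/cycle at 2 f1
  expect_error(lockin_demodulate(list(t = t3, x = rep(1, 512)), cfg),
               "sampling too sparse")
})

test_that("Bessel-series harmonics are linear in the Stokes vector", {
  cfg <- default_cfg()
  s1 <- c(1, 0.3, -0.2, 0.5); s2 <- c(1, -0.1, 0.6, -0.3)
  h1 <- sig_vec(analytic_harmonics(s1, cfg))
  h2 <- sig_vec(analytic_harmonics(s2, cfg))
  h12 <- sig_vec(analytic_harmonics(2.5 * s1 - 1.3 * s2, cfg))
  expect_equal(h12, 2.5 * h1 - 1.3 * h2, tolerance = 1e-12)
  ## unpolarised input: only the DC term survives
  expect_equal(sig_vec(analytic_harmonics(c(1, 0, 0, 0), cfg)),
               c(0.5, 0, 0, 0), tolerance = 1e-12)
})

test_that("numerical lock-in agrees with the Bessel-series oracle", {
  cfgs <- list(default_cfg(),
               polarimeter_config(A1 = 2.0, A2 = 2.6),
               polarimeter_config(alpha = 40 * pi / 180, beta = 0.5,
                                  f1 = 60, f2 = 44))
  states <- random_states(6, seed = 11)
  for (cfg in cfgs) {
    for (s in asplit(states, 1)) {
      num <- sig_vec(lockin_demodulate(simulate_intensity_series(s, cfg, 8192)))
      ana <- sig_vec(analytic_harmonics(s, cfg))
      expect_equal(num, ana, tolerance = 1e-8)
    }
  }
})

test_that("the signal response map is invertible with the expected sparsity", {
  A <- signal_matrix(default_cfg())
  K <- solve(A)
  zeros <- rbind(c(1, 4), c(2, 1), c(2, 4), c(3, 1), c(3, 4),
                 c(4, 1), c(4, 2), c(4, 3))
  expect_lt(max(abs(K[zeros])), 1e-8 * max(abs(K)))
  expect_s3_class(true_k_matrix(default_cfg()), "k_matrix")
})

test_that("configuration invariants are enforced", {
  expect_error(polarimeter_config(f1 = 50, f2 = 50), "distinct")
  expect_error(polarimeter_config(f1 = -1), "positive")
  expect_error(polarimeter_config(A1 = 0), "amplitudes")
  expect_warning(polarisation_state(1, 1, 1, 1), "unphysical")
  expect_error(polarisation_state(-1), "non-negative")
})
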