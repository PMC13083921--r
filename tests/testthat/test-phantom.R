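test_that("phantoms honour their construction anchors and determinism", {
  ## flat zero phantom
  ph0 <- generate_phantom(phantom_spec("flat", c(16, 16), seed = 1))
  expect_equal(ph0$truth$delta, matrix(0, 16, 16))
  expect_equal(ph0$truth$sigma, matrix(1, 16, 16))
  ## placental phantom peaks at 0.04 rad by construction
  php <- generate_phantom(phantom_spec("placenta_villi", c(96, 96), seed = 3))
  expect_equal(max(php$truth$delta), 0.04)
  ## dermis peaks at 1.00, keloid at 1.40 with Dp up to 0.96
  phd <- generate_phantom(phantom_spec("dermis", c(96, 96), seed = 3))
  expect_equal(max(phd$truth$delta), 1.00)
  phk <- generate_phantom(phantom_spec("keloid", c(96, 96), seed = 3))
  expect_equal(max(phk$truth$delta), 1.40, tolerance = 1e-6)
  expect_equal(max(sqrt(1 - 1 / phk$truth$sigma^2)), 0.96, tolerance = 1e-6)
  ## determinism: identical seed, identical phantom
  pha <- generate_phantom(phantom_spec("keloid", c(48, 48), seed = 9))
  phb <- generate_phantom(phantom_spec("keloid", c(48, 48), seed = 9))
  expect_identical(pha$truth, phb$truth)
  phc <- generate_phantom(phantom_spec("keloid", c(48, 48), seed = 10))
  expect_false(identical(pha$truth$delta, phc$truth$delta))
  expect_error(generate_phantom(phantom_spec("keloid", delta_peak = 4)), "pi")
})

test_that("substrate and tissue depolarisation defaults follow the anchors", {
  ph <- generate_phantom(phantom_spec("placenta_villi", c(64, 64), seed = 5))
  dp <- sqrt(1 - 1 / ph$truth$sigma^2)
  expect_equal(unique(round(dp[!ph$truth$tissue], 6)), 0.44)
  expect_equal(unique(round(dp[ph$truth$tissue], 6)), 0.37)
})

test_that("noiseless render followed by reconstruction recovers ground truth", {
  cfg <- polarimeter_config()
  K <- calibrate(simulate_calibration_set(canonical_states(), cfg))
  for (kind in c("placenta_villi", "dermis", "keloid")) {
    ph <- generate_phantom(phantom_spec(kind, c(48, 48), seed = 7))
    acq <- render_acquisition(ph, input = c(1, 0, 0, 1), cfg = cfg)
    img <- reconstruct_stokes(acq$signals, K)
    rm_ <- retardation_map(img, mode = "circular")
    expect_lt(max(abs(rm_$delta - ph$truth$delta)), 1e-6)
    sel <- ph$truth$delta > 1e-3   # axis only defined with retardation
    expect_lt(max(ang_diff_mod_pi(rm_$gamma[sel], ph$truth$gamma[sel])), 1e-6)
    Dp <- depolarisation_map(img)
    expect_lt(max(abs(Dp - sqrt(1 - 1 / ph$truth$sigma^2))), 1e-8)
  }
})

test_that("renders are seed-reproducible and emit the no-sample reference", {
  ph <- generate_phantom(phantom_spec("flat", c(8, 8), seed = 1,
                                      delta_flat = 0.3))
  ns <- noise_spec(read_noise_sd = 1e-3, seed = 21)
  a1 <- render_acquisition(ph, noise = ns)
  a2 <- render_acquisition(ph, noise = ns)
  expect_identical(a1$signals, a2$signals)
  a3 <- render_acquisition(ph, noise = noise_spec(1e-3, seed = 22))
  expect_false(identical(a1$signals$S_DC, a3$signals$S_DC))
  ## the reference acquisition carries the input state
  K <- true_k_matrix(polarimeter_config())
  ref <- render_acquisition(ph)$reference
  st <- stokes_from_signals(ref, K)
  expect_equal(as.vector(st$I), rep(1, 64), tolerance = 1e-9)
  expect_equal(as.vector(st$V), rep(1, 64), tolerance = 1e-9)
})

test_that("shot noise respects the photon scale", {
  ph <- generate_phantom(phantom_spec("flat", c(64, 64), seed = 1,
                                      delta_flat = 0.2))
  acq <- render_acquisition(ph, noise = noise_spec(0, photon_scale = 1e4,
                                                   seed = 5))
  dc <- as.vector(acq$signals$S_DC)
  dc0 <- as.vector(render_acquisition(ph)$signals$S_DC)
  ## Poisson: variance ~ mean / scale
  expect_equal(stats::sd(dc), sqrt(mean(dc0) / 1e4), tolerance = 0.15)
})

test_that("tuned read noise yields the requested retardation noise floor", {
  cfg <- polarimeter_config()
  sd_target <- 0.005
  rn <- read_noise_for_retardation_sd(sd_target, delta_bg = 0.11, cfg = cfg)
  ph <- generate_phantom(phantom_spec("flat", c(64, 64), seed = 2,
                                      delta_flat = 0.11))
  acq <- render_acquisition(ph, cfg = cfg,
                            noise = noise_spec(rn, seed = 31))
  img <- reconstruct_stokes(acq$signals, true_k_matrix(cfg))
  rm_ <- retardation_map(img, mode = "circular")
  expect_equal(stats::sd(rm_$delta), sd_target, tolerance = 0.2)
  expect_error(read_noise_for_retardation_sd(0.005, delta_bg = 0),
               "degenerate")
})
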