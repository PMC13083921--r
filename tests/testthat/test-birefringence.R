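test_that("sample Mueller matrix has the documented structure", {
  expect_equal(sample_mueller(0, 0.3, 1.7), diag(c(1.7, 1, 1, 1)))
  M <- sample_mueller(0.7, 0.3, 1)
  blk <- M[2:4, 2:4]
  expect_equal(blk %*% t(blk), diag(3), tolerance = 1e-12)
  expect_equal(det(blk), 1, tolerance = 1e-12)
  expect_error(sample_mueller(0.5, 0, sigma = 0.5), "sigma")
})

test_that("polarised propagation preserves the fully-polarised condition", {
  set.seed(10)
  n <- 50
  m <- sample_map(matrix(runif(n, 0, pi)), matrix(runif(n, 0, pi)), 1)
  th <- runif(1, 0, pi); ep <- runif(1, -pi / 4, pi / 4)
  s <- elliptical_state(ep, th)
  quv <- c(s[2], s[3], s[4]) / sqrt(sum(s[2:4]^2))
  out <- propagate(list(q = quv[1], u = quv[2], v = quv[3]), m)
  expect_equal(out$q^2 + out$u^2 + out$v^2, matrix(1, n, 1), tolerance = 1e-12)
  ## zero retardation leaves the polarised part unchanged
  m0 <- sample_map(matrix(0, 3, 3), matrix(1, 3, 3), 1)
  out0 <- propagate(list(q = quv[1], u = quv[2], v = quv[3]), m0)
  expect_equal(out0$q, matrix(quv[1], 3, 3))
  expect_equal(out0$v, matrix(quv[3], 3, 3))
})

test_that("circular illumination gives the closed-form transmitted components", {
  ## optic axis on the x-axis: q' = 0, u' = sin(delta), v' = cos(delta)
  d <- seq(0.1, 3, length.out = 7)
  m <- sample_map(matrix(d), matrix(0), 1)
  out <- propagate(list(q = 0, u = 0, v = 1), m)
  expect_equal(as.vector(out$q), rep(0, 7), tolerance = 1e-14)
  expect_equal(as.vector(out$u), sin(d), tolerance = 1e-14)
  expect_equal(as.vector(out$v), cos(d), tolerance = 1e-14)
})

test_that("retardation and axis recovery invert the circular forward model", {
  expect_equal(retardation_from_circular(1)[1], 0)
  expect_equal(retardation_from_circular(0)[1], pi / 2)
  ## clamping of noisy v' is counted
  d <- retardation_from_circular(c(1.01, 0.5, -1.02))
  expect_equal(attr(d, "n_clamped"), 2L)
  ## placental-scale round trip
  m <- sample_map(matrix(0.04), matrix(0.6), 1)
  out <- propagate(list(q = 0, u = 0, v = 1), m)
  expect_equal(retardation_from_circular(out$v)[1], 0.04, tolerance = 1e-12)
  ## axis recovery: gamma = 0 gives q' = 0, u' > 0
  expect_equal(axis_from_linear(0, 0.5)[1], 0)
  for (g_true in c(pi / 6, pi / 6 + pi / 2, 2.8)) {
    mg <- sample_map(matrix(0.5), matrix(g_true), 1)
    og <- propagate(list(q = 0, u = 0, v = 1), mg)
    expect_equal(ang_diff_mod_pi(axis_from_linear(og$q, og$u)[1], g_true), 0,
                 tolerance = 1e-12)
  }
  ## distinct recovery of gamma and gamma + pi/2
  m1 <- propagate(list(q = 0, u = 0, v = 1), sample_map(matrix(0.5), matrix(pi / 6), 1))
  m2 <- propagate(list(q = 0, u = 0, v = 1), sample_map(matrix(0.5), matrix(pi / 6 + pi / 2), 1))
  g1 <- axis_from_linear(m1$q, m1$u)[1]
  g2 <- axis_from_linear(m2$q, m2$u)[1]
  expect_gt(ang_diff_mod_pi(g1, g2), 1)
  ## axis undefined where the linear components vanish
  expect_true(is.na(axis_from_linear(0, 0)[1]))
})

test_that("round trip is exact over a retardation/orientation grid", {
  grid <- expand.grid(d = seq(0.01, 3.1, length.out = 16),
                      g = seq(0, pi, length.out = 17)[-17])
  m <- sample_map(matrix(grid$d), matrix(grid$g), 1)
  out <- propagate(list(q = 0, u = 0, v = 1), m)
  dh <- retardation_from_circular(out$v)
  gh <- axis_from_linear(out$q, out$u)
  expect_lt(max(abs(dh - grid$d)), 1e-10)
  expect_lt(max(ang_diff_mod_pi(as.vector(gh), grid$g)), 1e-10)
})

test_that("full inversion matches the shortcut under circular input", {
  set.seed(3)
  n <- 40
  d <- runif(n, 0.05, 3); g <- runif(n, 0, pi)
  out <- propagate(list(q = 0, u = 0, v = 1), sample_map(matrix(d), matrix(g), 1))
  inv <- retardation_full_inversion(out$q, out$u, out$v, c(0, 0, 1))
  expect_equal(as.vector(inv$delta), d, tolerance = 1e-8)
  expect_lt(max(ang_diff_mod_pi(as.vector(inv$gamma), g)), 1e-8)
  expect_true(all(inv$converged))
})

test_that("full inversion removes the elliptical-illumination bias", {
  ell <- 41 * pi / 180
  st <- elliptical_state(ell)
  quv <- c(st[2], st[3], st[4]) / sqrt(sum(st[2:4]^2))
  gams <- seq(0, pi, length.out = 37)[-37]
  out <- propagate(list(q = quv[1], u = quv[2], v = quv[3]),
                   sample_map(matrix(rep(1, length(gams))), matrix(gams), 1))
  inv <- retardation_full_inversion(out$q, out$u, out$v, quv)
  full_err <- abs(as.vector(inv$delta) - 1)
  circ_err <- abs(as.vector(retardation_from_circular(out$v)) - 1)
  expect_lt(max(full_err), 1e-6)
  expect_gt(max(circ_err), 0.05)       # the shortcut is visibly biased
  expect_true(all(full_err <= circ_err + 1e-12))
  expect_lt(max(ang_diff_mod_pi(as.vector(inv$gamma), gams)), 1e-6)
})

test_that("full inversion handles zero retardation by masking the axis", {
  out <- propagate(list(q = 0, u = 0, v = 1),
                   sample_map(matrix(0), matrix(0.4), 1))
  inv <- retardation_full_inversion(out$q, out$u, out$v, c(0, 0, 1))
  expect_equal(inv$delta[1], 0, tolerance = 1e-10)
  expect_true(is.na(inv$gamma[1]))
  expect_error(retardation_full_inversion(0, 0, 1, c(1, 1, 1)), "normalised")
})

test_that("circular-input error profile behaves as the model predicts", {
  ## exact circular limit: zero error everywhere
  p45 <- circular_input_error_profile(1.0, pi / 4)
  expect_lt(attr(p45, "max_abs_error"), 1e-12)
  ## 41 degree illumination: nonzero orientation-dependent error
  p41 <- circular_input_error_profile(1.0, 41 * pi / 180)
  expect_gt(attr(p41, "max_abs_error"), 0.05)
  expect_gt(diff(range(p41$error)), 0.05)
  ## envelope periodic with period pi/2: window maxima agree
  grid <- seq(0, pi, length.out = 721)[-721]
  p <- circular_input_error_profile(1.0, 41 * pi / 180, gammas = grid)
  w1 <- max(abs(p$error[grid < pi / 2]))
  w2 <- max(abs(p$error[grid >= pi / 2]))
  expect_equal(w1, w2, tolerance = 1e-3)
  expect_error(circular_input_error_profile(1, 0), "ellipticity")
})

test_that("propagating a depolarising sample yields P = 1/sigma", {
  sig <- c(1.2, 2, 3.571)
  m <- sample_map(matrix(0.5, 1, 3), matrix(0.7, 1, 3),
                  matrix(sig, 1, 3))
  out <- propagate(list(i = 1, q = 0, u = 0, v = 1), m)
  img <- stokes_image(out$i, out$q, out$u, out$v)
  P <- dop_map(img)
  expect_equal(as.vector(P), 1 / sig, tolerance = 1e-12)
  expect_equal(as.vector(depolarisation_map(img)), sqrt(1 - 1 / sig^2),
               tolerance = 1e-12)
})

test_that("retardation_map wraps both inversion modes", {
  ph <- generate_phantom(phantom_spec("placenta_villi", c(24, 24), seed = 2))
  acq <- render_acquisition(ph)
  rm_c <- retardation_map(acq$stokes_truth, mode = "circular")
  ## arccos near v' = 1 limits absolute precision for near-zero retardation
  expect_lt(max(abs(rm_c$delta - ph$truth$delta)), 1e-6)
  rm_f <- retardation_map(acq$stokes_truth, input = c(1, 0, 0, 1),
                          mode = "full")
  expect_lt(max(abs(rm_f$delta - ph$truth$delta)), 1e-6)
  expect_error(retardation_map(acq$stokes_truth, mode = "full"), "input")
})

test_that("background correction recovers baseline and local contrast", {
  map <- matrix(0.11, 40, 40)
  map[15:20, 15:20] <- 0.15
  bc <- background_correct(map, region = c(1, 1, 10, 10))
  expect_equal(bc$baseline, 0.11)
  expect_equal(bc$corrected[16, 16], 0.04)
  expect_equal(bc$corrected[1, 1], 0)
  ## modal estimator agrees on this fixture
  bm <- background_correct(map, method = "mode")
  expect_equal(bm$baseline, 0.11, tolerance = 1e-3)
  ## all-zero map: baseline 0, unchanged
  z <- background_correct(matrix(0, 5, 5), region = c(1, 1, 2, 2))
  expect_equal(z$baseline, 0)
  expect_equal(z$corrected, matrix(0, 5, 5))
  expect_error(background_correct(map, region = c(38, 38, 10, 10)), "outside")
  expect_error(background_correct(map, region = NULL), "region")
})
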