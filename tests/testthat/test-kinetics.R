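test_that("kinetic trace simulation is exact in the noiseless limit and seeded", {
  t <- seq(0, 30, length.out = 50)
  tr <- simulate_kinetic_trace(A = 2, R = 0.1, times = t, noise_sd = 0)
  expect_equal(tr$y, 2 * exp(0.1 * t), tolerance = 1e-12)
  a <- simulate_kinetic_trace(1, 0.2, t, noise_sd = 0.05, seed = 4)
  b <- simulate_kinetic_trace(1, 0.2, t, noise_sd = 0.05, seed = 4)
  expect_identical(a$y, b$y)
  expect_error(simulate_kinetic_trace(1, 1, numeric(0)),
               class = "invalid_argument")
})

test_that("exponential growth fits recover parameters", {
  t <- seq(0, 10, length.out = 40)
  tr <- kinetic_trace(t, 2 * exp(0.5 * t))
  fit <- fit_exponential(tr, mode = "growth")
  expect_equal(fit$A, 2, tolerance = 1e-6)
  expect_equal(fit$R, 0.5, tolerance = 1e-6)
  expect_equal(fit$time_constant, 2, tolerance = 1e-6)
})

test_that("aggregation-scale time constants are recovered at 1% noise", {
  t <- seq(0, 30, length.out = 100)
  tr <- simulate_kinetic_trace(A = 1, R = 1 / 4.8, times = t, noise_sd = 0.01,
                               seed = 12)
  fit <- fit_exponential(tr, mode = "growth")
  expect_lt(abs(fit$time_constant / 4.8 - 1), 0.02)
})

test_that("a flat trace yields a rate confidence interval covering zero", {
  t <- seq(0, 30, length.out = 100)
  tr <- simulate_kinetic_trace(A = 1, R = 0, times = t, noise_sd = 0.01,
                               seed = 13)
  fit <- suppressWarnings(fit_exponential(tr, mode = "growth"))
  expect_lt(abs(fit$R), 2 * fit$se_R)
})

test_that("FRAP recovery fits report tau and the ln2-corrected half-time", {
  t <- seq(0, 30, length.out = 120)
  y <- 0.9 - 0.7 * exp(-t / 5)
  tr <- simulate_kinetic_trace(1, 0, t, seed = 1) # container only
  tr$y <- y + withr::with_seed(14, rnorm(length(t), 0, 0.02))
  fit <- fit_exponential(tr, mode = "frap_recovery")
  expect_lt(abs(fit$time_constant / 5 - 1), 0.04)
  expect_lt(abs(fit$F_inf - 0.9), 0.02)
  expect_equal(fit$half_time, log(2) * fit$time_constant, tolerance = 1e-9)
})

test_that("exponential fits are scale-equivariant", {
  t <- seq(0, 20, length.out = 60)
  tr <- simulate_kinetic_trace(1.5, 0.2, t, noise_sd = 0.01, seed = 15)
  f1 <- fit_exponential(tr, mode = "growth")
  tr2 <- tr; tr2$y <- tr$y * 7
  f2 <- fit_exponential(tr2, mode = "growth")
  expect_equal(f2$A / f1$A, 7, tolerance = 1e-6)
  expect_equal(f2$R, f1$R, tolerance = 1e-9)
})

test_that("FRAP normalization cancels acquisition bleaching exactly", {
  t <- seq(0, 20, by = 0.5)
  bleach <- exp(-0.1 * t)
  recovery <- c(rep(1, 3), 0.9 - 0.6 * exp(-(t[-(1:3)] - t[4]) / 4))
  roi <- kinetic_trace(t, bleach * recovery, units = "s")
  ref <- kinetic_trace(t, bleach, units = "s")
  out <- normalize_frap(roi, ref, n_prebleach = 3)
  expect_equal(out$y, recovery, tolerance = 1e-12)
  expect_equal(mean(out$y[1:3]), 1, tolerance = 1e-12)
  # roi == ref gives the flat unit trace
  flat <- normalize_frap(ref, ref, n_prebleach = 3)
  expect_equal(flat$y, rep(1, length(t)), tolerance = 1e-12)
  # invariance to any common multiplicative function of t
  g <- 1 + 0.3 * sin(t)
  roi2 <- kinetic_trace(t, roi$y * g, units = "s")
  ref2 <- kinetic_trace(t, ref$y * g, units = "s")
  expect_equal(normalize_frap(roi2, ref2, 3)$y, out$y, tolerance = 1e-12)
  expect_error(normalize_frap(roi, ref, 0), class = "invalid_argument")
  ref0 <- kinetic_trace(t, c(0, bleach[-1]), units = "s")
  expect_error(normalize_frap(roi, ref0, 3), class = "invalid_input")
})

test_that("solubility fractions follow the fraction-of-total reading", {
  expect_equal(solubility_fraction(0.8, 0.2), 80)
  expect_equal(solubility_fraction(0.5, 0), 100)
  expect_equal(solubility_fraction(0, 0.7), 0)
  expect_equal(solubility_fraction(0.5, 0.25, denominator = "pellet"), 200)
  expect_error(solubility_fraction(0, 0), class = "undefined_ratio")
})

test_that("calibration lines fit, predict and invert exactly", {
  # points exactly on log10(Mw) = -0.5 t + 8
  t <- c(6, 8, 10, 12)
  mw <- 10^(-0.5 * t + 8)
  line <- fit_calibration(t, mw, transform = "log10_response")
  expect_equal(line$slope, -0.5, tolerance = 1e-9)
  expect_equal(invert_calibration(line, 1e3), 10, tolerance = 1e-9)
  expect_equal(predict_calibration(line, 10), 1e3, tolerance = 1e-6)
  # identity transform, exact line
  l2 <- fit_calibration(c(0, 1, 2), c(1, 3, 5))
  expect_equal(l2$slope, 2, tolerance = 1e-12)
  expect_equal(l2$intercept, 1, tolerance = 1e-12)
  # two points interpolate with zero residual
  l3 <- fit_calibration(c(1, 3), c(2, 8))
  expect_equal(predict_calibration(l3, c(1, 3)), c(2, 8), tolerance = 1e-12)
  # predict-then-invert identity over the fitted range
  xs <- seq(6, 12, by = 0.5)
  expect_equal(invert_calibration(line, predict_calibration(line, xs)), xs,
               tolerance = 1e-9)
  expect_error(fit_calibration(c(2, 2, 2), c(1, 2, 3)),
               class = "invalid_argument")
})

test_that("nuclear concentration arithmetic and guards", {
  expect_equal(nuclear_concentration(2.2e-16, 1e6, transfection_eff = 1), 1e-9,
               tolerance = 1e-12)
  c1 <- nuclear_concentration(1e-15, 1e6, transfection_eff = 0.8)
  c2 <- nuclear_concentration(1e-15, 1e6, transfection_eff = 0.4)
  expect_equal(c2 / c1, 2, tolerance = 1e-12)
  expect_error(nuclear_concentration(1e-15, 1e6, transfection_eff = 0),
               class = "invalid_argument")
})
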