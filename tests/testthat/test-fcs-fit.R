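test_that("fcs_model evaluates its closed forms", {
  expect_equal(fcs_model(0, C = 10, D = 430, w0 = 0.3, z0 = 1.5),
               1 / (pi^1.5 * 0.3^2 * 1.5 * 10), tolerance = 1e-12)
  expect_equal(round(fcs_model(0, C = 10, D = 430, w0 = 0.3, z0 = 1.5), 4),
               0.1330)
  # lateral half-decay time in the cylindrical limit: tau = w0^2/(4D)
  tau_half <- 0.3^2 / (4 * 430)
  expect_equal(tau_half, 52.3e-6, tolerance = 1e-2)
  g <- fcs_model(tau_half, C = 10, D = 430, w0 = 0.3, z0 = 1e6)
  expect_equal(g / fcs_model(0, C = 10, D = 430, w0 = 0.3, z0 = 1e6), 0.5,
               tolerance = 1e-9)
  # monotone decreasing, vanishing at large tau and C
  taus <- 10^seq(-7, 1, by = 0.25)
  g <- fcs_model(taus, C = 2, D = 100, w0 = 0.3, z0 = 1.5)
  expect_true(all(diff(g) < 0))
  expect_lt(fcs_model(1e6, C = 2, D = 100, w0 = 0.3, z0 = 1.5), 1e-10)
  expect_lt(fcs_model(0, C = 1e12, D = 100, w0 = 0.3, z0 = 1.5), 1e-10)
  expect_error(fcs_model(-1, C = 1, D = 1, w0 = 0.3, z0 = 1.5),
               class = "invalid_argument")
})

test_that("fit_fcs recovers noiseless model curves to 1e-6 and is a fixed point", {
  opt <- default_optics()
  taus <- 10^seq(-6, 0, length.out = 60)
  cv <- correlation_curve(taus, fcs_model(taus, C = 2, D = 430, w0 = opt$w0,
                                          z0 = opt$z0))
  fit <- fit_fcs(cv, opt)
  expect_equal(fit$C, 2, tolerance = 1e-6)
  expect_equal(fit$D, 430, tolerance = 1e-6)
  refit <- fit_fcs(cv, opt, init = list(C = fit$C, D = fit$D))
  expect_equal(refit$C, fit$C, tolerance = 1e-8)
  expect_equal(refit$D, fit$D, tolerance = 1e-8)
})

test_that("flat curves raise an amplitude-degenerate error", {
  taus <- 10^seq(-6, 0, length.out = 30)
  flat <- correlation_curve(taus, rnorm(30, 0, 1e-7),
                            se = rep(1e-6, 30))
  expect_error(fit_fcs(flat, default_optics()),
               class = "amplitude_degenerate")
})

test_that("fit_fcs recovers simulated concentration and diffusion at 60 s", {
  sp <- species_spec("donor_only", conc = 6.65, D = 50, eps = 1e4)
  st <- simulate_photon_stream(sp, default_optics(), duration = 60,
                               dt = suggest_dt(50), seed = 103)
  cv <- compute_correlation(st, list(channel = "D", gate = "Dex"),
                            lag_range = c(2 * suggest_dt(50), 0.5))
  fit <- fit_fcs(cv, default_optics())
  expect_lt(abs(fit$C / 6.65 - 1), 0.1)
  expect_lt(abs(fit$D / 50 - 1), 0.1)
})

test_that("optics calibration inverts the calibration curve", {
  opt <- default_optics()
  taus <- 10^seq(-6, 0, length.out = 60)
  cv <- correlation_curve(taus, fcs_model(taus, C = 2, D = 430, w0 = 0.3,
                                          z0 = 1.5))
  cal <- calibrate_optics(cv, D_ref = 430, shape_ratio = 5)
  expect_equal(cal$w0, 0.3, tolerance = 0.01)
  # doubling D_ref rescales w0 by sqrt(2) (diffusion-term scaling law)
  cal2 <- calibrate_optics(cv, D_ref = 860, shape_ratio = 5)
  expect_equal(cal2$w0 / cal$w0, sqrt(2), tolerance = 1e-3)
  expect_error(calibrate_optics(cv, D_ref = -1), class = "invalid_argument")
})

test_that("fitted concentration scales with the true concentration", {
  opt <- default_optics()
  ratios <- c(1, 2, 4)
  fits <- vapply(seq_along(ratios), function(i) {
    sp <- species_spec("donor_only", conc = 1.5 * ratios[i], D = 100,
                       eps = 1e4)
    st <- simulate_photon_stream(sp, opt, duration = 15,
                                 dt = suggest_dt(100), seed = 300 + i)
    cv <- compute_correlation(st, list(channel = "D", gate = "Dex"),
                              lag_range = c(2 * suggest_dt(100), 0.5))
    fit_fcs(cv, opt)$C
  }, numeric(1))
  expect_lt(max(abs(fits / fits[1] / ratios - 1)), 0.15)
})

test_that("fitted parameters are brightness-invariant for one species", {
  opt <- default_optics()
  fits <- lapply(c(1e4, 2e4), function(eps) {
    sp <- species_spec("donor_only", conc = 3, D = 100, eps = eps)
    st <- simulate_photon_stream(sp, opt, duration = 15,
                                 dt = suggest_dt(100), seed = 42)
    cv <- compute_correlation(st, list(channel = "D", gate = "Dex"),
                              lag_range = c(2 * suggest_dt(100), 0.5))
    fit_fcs(cv, opt)
  })
  expect_lt(abs(fits[[2]]$C - fits[[1]]$C),
            3 * sqrt(fits[[1]]$se_C^2 + fits[[2]]$se_C^2) + 0.05 * fits[[1]]$C)
  expect_lt(abs(fits[[2]]$D - fits[[1]]$D),
            3 * sqrt(fits[[1]]$se_D^2 + fits[[2]]$se_D^2) + 0.05 * fits[[1]]$D)
})
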