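test_that("zero-length acquisition yields an empty stream, bad inputs error", {
  opt <- default_optics()
  sp <- species_spec("donor_only", conc = 1, D = 50, eps = 1e4)
  st <- simulate_photon_stream(sp, opt, duration = 0, seed = 1)
  expect_length(st$times, 0)
  expect_error(simulate_photon_stream(sp, opt, duration = -1, seed = 1),
               class = "invalid_argument")
  expect_error(simulate_photon_stream(sp, opt, duration = 1, dt = 0, seed = 1),
               class = "invalid_argument")
  expect_error(simulate_photon_stream(sp, opt, duration = 1, seed = 1,
                                      box = c(0.5, 0.5, 1)),
               class = "invalid_argument")
  expect_error(simulate_photon_stream(list(), optical_config(bg_rate = 0),
                                      duration = 1, seed = 1),
               class = "invalid_argument")
})

test_that("streams satisfy their invariants and are reproducible", {
  opt <- optical_config(bg_rate = 2000)
  sp <- species_spec("dual", conc = 2, D = 50, eps = 1e4, efret = 0.5)
  st1 <- simulate_photon_stream(sp, opt, duration = 2, seed = 7)
  st2 <- simulate_photon_stream(sp, opt, duration = 2, seed = 7)
  st3 <- simulate_photon_stream(sp, opt, duration = 2, seed = 8)
  expect_identical(st1$times, st2$times)
  expect_identical(st1$channel, st2$channel)
  expect_identical(st1$gate, st2$gate)
  expect_false(identical(st1$times, st3$times))
  expect_false(is.unsorted(st1$times))
  expect_gte(min(st1$times), 0)
  expect_lte(max(st1$times), 2)
  expect_setequal(as.character(unique(st1$channel)), c("D", "A"))
  expect_setequal(as.character(unique(st1$gate)), c("Dex", "Aex"))
  # photon-count conservation: channel-assigned counts sum to the total
  expect_identical(sum(table(st1$channel)), length(st1$times))
  expect_identical(sum(table(st1$gate)), length(st1$times))
})

test_that("an immobile emitter at the beam centre has the closed-form rate", {
  # at W = 1 the per-step Poisson mean is eps * dt = 0.1
  opt <- default_optics()
  sp <- species_spec("donor_only", conc = 1 / (2.4 * 2.4 * 6), D = 1e-9,
                     eps = 1e4)
  st <- simulate_photon_stream(sp, opt, duration = 10, dt = 1e-5, seed = 3,
                               positions0 = matrix(0, 1, 3))
  n_steps <- 1e6
  rate <- length(st$times) / n_steps
  se <- sqrt(0.1 / n_steps)
  expect_lt(abs(rate - 0.1), 3 * se)
})

test_that("expected total counts match the Gaussian-volume integral", {
  opt <- default_optics()
  w0 <- opt$w0; z0 <- opt$z0
  sp <- species_spec("donor_only", conc = 6.65, D = 100, eps = 1e4)
  st <- simulate_photon_stream(sp, opt, duration = 10, dt = 2e-5, seed = 5)
  expected <- 10 * 6.65 * 1e4 * (pi / 2)^1.5 * w0^2 * z0
  expect_lt(abs(length(st$times) / expected - 1), 0.05)
})

test_that("background-only streams are uncorrelated at all lags", {
  opt <- optical_config(bg_rate = 2e4)
  st <- simulate_photon_stream(list(), opt, duration = 20, seed = 9)
  cv <- compute_correlation(st, list(channel = "D"), lag_range = c(1e-4, 1))
  ok <- is.finite(cv$se) & cv$se > 0
  # individually a 3 s.e. bound holds for ~99.7% of lags; over the whole
  # ladder allow the expected handful of marginal exceedances
  expect_gte(mean(abs(cv$G[ok]) < 3 * cv$se[ok] + 1e-6), 0.97)
  expect_true(all(abs(cv$G[ok]) < 6 * cv$se[ok] + 1e-6))
})

test_that("photon stream text round trip is lossless", {
  opt <- optical_config(bg_rate = 500)
  sp <- species_spec("dual", conc = 1, D = 50, eps = 5e3, efret = 0.4)
  st <- simulate_photon_stream(sp, opt, duration = 1, seed = 11)
  path <- tempfile(fileext = ".tsv")
  write_photon_stream(st, path)
  st2 <- read_photon_stream(path)
  expect_identical(st$times, st2$times)
  expect_identical(st$channel, st2$channel)
  expect_identical(st$gate, st2$gate)
  expect_identical(st$duration, st2$duration)
  unlink(path)
})

test_that("the internal normal generator matches N(0,1) moments and tails", {
  z <- flucbridge:::.rng_normal_cpp(1e6, 42)
  expect_lt(abs(mean(z)), 4 / sqrt(1e6))
  expect_lt(abs(sd(z) - 1), 0.005)
  expect_lt(abs(mean(z^3)), 0.02)
  expect_lt(abs(mean(z^4) - 3), 0.05)
  expect_lt(abs(mean(abs(z) > 3) / (2 * pnorm(-3)) - 1), 0.15)
  # decile chi-square against the exact normal quantiles
  q <- qnorm(seq(0.1, 0.9, by = 0.1))
  counts <- table(cut(z, c(-Inf, q, Inf)))
  chi <- sum((counts - 1e5)^2 / 1e5)
  expect_lt(chi, 40) # dof 9, generous
})
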