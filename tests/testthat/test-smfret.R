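test_that("intensity corrections reproduce the worked FRET arithmetic", {
  # I_A = 100 - 0.03*200 - 0.01*300 = 91; E = 91/(91 + 200)
  expect_equal(fret_efficiency(100, 200, 300), 91 / 291, tolerance = 1e-12)
  expect_equal(round(fret_efficiency(100, 200, 300), 4), 0.3127)
  # a fully corrected donor-only bin has E = 0
  expect_equal(fret_efficiency(0.03 * 200 + 0.01 * 300, 200, 300), 0)
  # invariance under uniform intensity rescaling
  e1 <- fret_efficiency(120, 80, 50)
  e2 <- fret_efficiency(120 * 7, 80 * 7, 50 * 7)
  expect_equal(e1, e2, tolerance = 1e-12)
  # with gamma = 1 and no crosstalk, E(IA, ID) + E(ID, IA) = 1
  eA <- fret_efficiency(120, 80, 0, l = 0, d = 0)
  eD <- fret_efficiency(80, 120, 0, l = 0, d = 0)
  expect_equal(eA + eD, 1, tolerance = 1e-12)
})

test_that("gating and binning select bins by total donor-gate signal", {
  opt <- optical_config(bg_rate = 1000)
  st <- simulate_photon_stream(list(), opt, duration = 20, seed = 41)
  all_bins <- gate_and_bin(st, threshold = 0)
  expect_true(all(all_bins$selected))
  expect_equal(length(all_bins$I_D), 40000)
  # pure 1 kHz/channel background: P(total >= 15 per 500 us) is astronomically
  # small, so essentially no bin is selected
  b15 <- gate_and_bin(st, threshold = 15)
  expect_lt(mean(b15$selected), 1e-4)
})

test_that("histogram events equal the number of selected bins", {
  sp <- species_spec("dual", conc = 0.05, D = 50, eps = 2e5, efret = 0.5)
  st <- simulate_photon_stream(sp, default_optics(), duration = 5,
                               dt = suggest_dt(50), seed = 43)
  bins <- gate_and_bin(st)
  h <- fret_histogram(bins, n_gauss = 1)
  expect_equal(sum(h$counts), h$n_events)
  expect_equal(h$n_events, sum(bins$selected))
})

test_that("a simulated dual species is recovered at its FRET efficiency", {
  sp <- species_spec("dual", conc = 0.05, D = 50, eps = 2e5, efret = 0.75)
  st <- simulate_photon_stream(sp, default_optics(), duration = 15,
                               dt = suggest_dt(50), seed = 45)
  bins <- gate_and_bin(st)
  h <- fret_histogram(bins, n_gauss = 1)
  expect_false(is.null(h$gaussians))
  expect_lt(abs(h$gaussians$mean[1] - 0.75), 0.02)
})

test_that("empty selection raises and raw histogram survives fit failure", {
  opt <- optical_config(bg_rate = 100)
  st <- simulate_photon_stream(list(), opt, duration = 6, seed = 47)
  bins <- gate_and_bin(st, threshold = 1e6)
  expect_error(fret_histogram(bins), class = "empty_input")
})

test_that("denaturation profiles separate linear drift from two-state transitions", {
  concs <- seq(0, 7, by = 0.5)
  fake_hist <- function(mu) {
    structure(list(gaussians = data.frame(mean = mu, sd = 0.05,
                                          amplitude = 100,
                                          se_mean = 0.005, area = 100)),
              class = "fret_histogram")
  }
  # non-cooperative: linear decrease 0.8 -> 0.4 (with measurement jitter)
  mus_lin <- withr::with_seed(7, 0.8 - 0.4 * concs / 7 +
                                rnorm(length(concs), 0, 0.004))
  prof_lin <- denaturation_profile(lapply(mus_lin, fake_hist), concs)
  expect_identical(prof_lin$model_preferred, "linear")
  expect_true(prof_lin$cooperativity_ci[1] <= 0 &&
                prof_lin$cooperativity_ci[2] >= 0)
  # cooperative: sharp two-state step at 3 M
  mus_sig <- withr::with_seed(8,
    0.8 - 0.4 / (1 + exp(-(concs - 3) / 0.2)) +
      rnorm(length(concs), 0, 0.004))
  prof_sig <- denaturation_profile(lapply(mus_sig, fake_hist), concs)
  expect_identical(prof_sig$model_preferred, "sigmoid")
  expect_lt(abs(prof_sig$midpoint - 3), 0.2)
  # identical histograms: flat profile with zero slope
  prof_flat <- denaturation_profile(lapply(rep(0.6, length(concs)), fake_hist),
                                    concs)
  expect_equal(prof_flat$linear_slope, 0, tolerance = 1e-12)
  expect_error(denaturation_profile(lapply(mus_lin[1:3], fake_hist),
                                    concs[1:3]),
               class = "invalid_argument")
})
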