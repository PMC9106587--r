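#' Canned recovery experiments at the study's conditions
#'
#' These functions run complete simulate-measure-fit cycles at fixed,
#' documented conditions and return tidy summaries. They are the single
#' source of the configurations used by the regression tests, the analysis
#' scripts and the acceptance report.
#'
#' `expt_fcs_recovery` simulates freely diffusing single-labelled particles
#' at 6.65 particles/um^3 in a calibrated observation volume
#' (`w0 = 0.3` um, `z0 = 1.5` um) for 60 s per run, over a panel of diffusion
#' coefficients spanning small dyes to protein assemblies, computes the
#' multi-tau autocorrelation and fits the single-species model.
#'
#' @param D_values Diffusion coefficients to simulate (um^2/s).
#' @param conc True concentration (particles/um^3).
#' @param n_seeds Independent replicate runs per `D`.
#' @param duration Acquisition length per run (s).
#' @param eps Fluorophore brightness (counts/s at beam centre).
#' @param seed_base Integer; replicate seeds are derived from it.
#' @return Data frame with one row per run: `D_true`, `seed`, `C_hat`,
#'   `D_hat`, and the relative errors `C_err`, `D_err`.
#' @export
expt_fcs_recovery <- function(D_values = c(25, 100, 430), conc = 6.65,
                              n_seeds = 5, duration = 60, eps = 1e4,
                              seed_base = 1L) {
  opt <- optical_config()
  rows <- list()
  for (D in D_values) {
    dt <- suggest_dt(D, opt$w0)
    for (i in seq_len(n_seeds)) {
      seed <- (seed_base * 131L + round(D) * 7L + i) %% .Machine$integer.max
      sp <- species_spec("donor_only", conc = conc, D = D, eps = eps)
      st <- simulate_photon_stream(sp, opt, duration = duration, dt = dt,
                                   seed = seed)
      cv <- compute_correlation(st, list(channel = "D", gate = "Dex"),
                                lag_range = c(2 * dt, 0.5))
      fit <- fit_fcs(cv, opt)
      rows[[length(rows) + 1]] <- data.frame(
        D_true = D, seed = seed, C_hat = fit$C, D_hat = fit$D,
        C_err = fit$C / conc - 1, D_err = fit$D / D - 1)
    }
  }
  do.call(rbind, rows)
}

#' @rdname expt_fcs_recovery
#'
#' @details `expt_fccs_bridging` mimics the dual-colour DNA-bridging
#' cross-correlation measurement: free donor-labelled and acceptor-labelled
#' DNA at 2.8 particles/um^3 each, plus (optionally) slower double-labelled
#' bridged complexes, acquired for 60 s; the three correlation curves are
#' fitted simultaneously.
#'
#' @param dual_conc Density of dual-labelled complexes (um^-3); 1.2 makes
#'   them 30% of the donor-bearing particles.
#' @param free_conc Density of each free species (um^-3).
#' @param D_free,D_dual Diffusion coefficients (um^2/s).
#' @param seed Integer seed.
#' @export
expt_fccs_bridging <- function(dual_conc = 1.2, free_conc = 2.8,
                               D_free = 50, D_dual = 15, duration = 60,
                               seed = 1L) {
  opt <- optical_config()
  dt <- suggest_dt(D_free, opt$w0)
  sp <- list(species_spec("donor_only", conc = free_conc, D = D_free,
                          eps = 2e4),
             species_spec("acceptor_only", conc = free_conc, D = D_free,
                          eps = 2e4))
  if (dual_conc > 0) {
    sp <- c(sp, list(species_spec("dual", conc = dual_conc, D = D_dual,
                                  eps = 2e4, efret = 0.15)))
  }
  st <- simulate_photon_stream(sp, opt, duration = duration, dt = dt,
                               seed = seed)
  lr <- c(2 * dt, 0.5)
  Ga <- compute_correlation(st, list(channel = "A", gate = "Aex"),
                            lag_range = lr)
  Gd <- compute_correlation(st, list(channel = "D", gate = "Dex"),
                            lag_range = lr)
  Gx <- compute_correlation(st, list(channel = "D", gate = "Dex"),
                            list(channel = "A", gate = "Aex"), lag_range = lr)
  fit <- fit_fccs(Ga, Gd, Gx, opt)
  fit$dual_fraction <- fit$Cad / (fit$Cd + fit$Cad)
  fit$dual_fraction_true <- dual_conc / (free_conc + dual_conc)
  fit
}

#' @rdname expt_fcs_recovery
#'
#' @details `expt_fret_peak` measures a dilute dual-labelled species in
#' burst mode (500-us bins, mean + 3 sd selection) and fits one Gaussian to
#' the corrected FRET-efficiency histogram.
#'
#' @param efret True FRET efficiency of the dual species.
#' @export
expt_fret_peak <- function(efret = 0.75, duration = 15, seed = 1L) {
  opt <- optical_config()
  sp <- species_spec("dual", conc = 0.05, D = 50, eps = 2e5, efret = efret)
  st <- simulate_photon_stream(sp, opt, duration = duration,
                               dt = suggest_dt(50), seed = seed)
  h <- fret_histogram(gate_and_bin(st), n_gauss = 1)
  list(peak_mean = h$gaussians$mean[1], peak_se = h$gaussians$se_mean[1],
       n_events = h$n_events)
}

#' @rdname expt_fcs_recovery
#'
#' @details `expt_fret_linearity` is the desk-scale analogue of titrating a
#' DNA-bridging factor: mixtures of donor-only DNA and a fraction `f` of
#' bridged (dual-labelled, `E = 0.15`) complexes are measured in burst mode
#' and the fitted non-zero FRET-peak area is regressed against `f`. A large
#' simulation box keeps the sparse bridged species' particle number well
#' resolved.
#'
#' @param fractions Bridged fractions to simulate.
#' @return `expt_fret_linearity`: list with the per-fraction table and the
#'   `r_squared` of the area-vs-fraction regression.
#' @export
expt_fret_linearity <- function(fractions = c(0.05, 0.1, 0.15, 0.2, 0.3, 0.4),
                                duration = 240, seed_base = 1L) {
  opt <- optical_config()
  box <- c(12, 12, 24)
  ctot <- 0.08
  edges <- seq(-0.2, 1.2, by = 0.025)
  centers <- (edges[-1] + edges[-length(edges)]) / 2
  hists <- lapply(seq_along(fractions), function(i) {
    f <- fractions[i]
    sp <- list(species_spec("donor_only", conc = ctot * (1 - f), D = 50,
                            eps = 4e5),
               species_spec("dual", conc = ctot * f, D = 30, eps = 4e5,
                            efret = 0.15))
    st <- simulate_photon_stream(sp, opt, duration = duration,
                                 dt = suggest_dt(50),
                                 seed = (seed_base * 977L + i) %%
                                   .Machine$integer.max,
                                 box = box)
    fret_histogram(gate_and_bin(st), n_gauss = 2, edges = edges,
                   init_means = c(0, 0.15))
  })
  # titration-series analysis: the two component shapes (unbridged zero peak,
  # bridged peak near 0.15) are shared across the series, so fit them once on
  # the pooled histogram and then fit only the per-condition amplitudes
  pooled_counts <- Reduce(`+`, lapply(hists, `[[`, "counts"))
  pool_fit <- fit_gauss_counts(centers, pooled_counts, n_gauss = 2L,
                               edges = edges, init_means = c(0, 0.15))
  g1 <- exp(-(centers - pool_fit$mean[1])^2 / (2 * pool_fit$sd[1]^2))
  g2 <- exp(-(centers - pool_fit$mean[2])^2 / (2 * pool_fit$sd[2]^2))
  rows <- lapply(seq_along(fractions), function(i) {
    counts <- hists[[i]]$counts
    amp <- coef(lm(counts ~ 0 + g1 + g2))
    data.frame(fraction = fractions[i], n_events = hists[[i]]$n_events,
               fret_peak_area = max(amp[["g2"]], 0) * pool_fit$sd[2] *
                 sqrt(2 * pi))
  })
  tab <- do.call(rbind, rows)
  r2 <- summary(lm(fret_peak_area ~ fraction, data = tab))$r.squared
  list(table = tab, r_squared = r2,
       peak_means = pool_fit$mean, peak_sds = pool_fit$sd)
}

#' @rdname expt_fcs_recovery
#'
#' @details `expt_binding_site_contacts` plants binding-site anchors with a
#' known pairwise contact enrichment on a deeply sequenced 100-Mb synthetic
#' chromosome (25-kb bins, distance-decay exponent -1), ICE-balances the
#' map and aggregates contacts between anchors separated by at least 10 Mb,
#' where the local background is flat; the canonical 250-kb/25-kb scan gives
#' 400 background bin-bin contacts per pair.
#'
#' @param anchor_fold Planted anchor-anchor contact enrichment.
#' @param depth Sampled read pairs.
#' @export
expt_binding_site_contacts <- function(anchor_fold = 3, depth = 1e9,
                                       seed = 1L) {
  anchors <- seq(400, 3600, by = 100) # every 2.5 Mb, clear of the ends
  spec <- contact_map_spec(length_bp = 100e6, resolution = 25e3,
                           ps_exponent = -1, anchor_bins = anchors,
                           anchor_fold = anchor_fold, depth = depth,
                           seed = seed)
  sim <- simulate_contact_map(spec)
  bal <- ice_normalize(sim$matrix)
  ag <- pairwise_aggregate(bal, sim$anchors, min_sep = 10e6)
  flank <- ag$grid
  ctr <- (nrow(flank) + 1) / 2
  flank[ctr, ctr] <- NA
  list(aggregate = ag, center_score_mean = mean(ag$center_scores),
       flank_mean = mean(flank, na.rm = TRUE),
       flank_max_dev = max(abs(flank - 1), na.rm = TRUE),
       background_pair_count = unique(ag$background_pair_count))
}
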