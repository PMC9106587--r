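#!/usr/bin/env Rscript
# Dual-colour cross-correlation: DNA bridging shows up as a nonzero
# cross-correlation amplitude and a slower co-diffusing complex.
library(flucbridge)
dir.create("results", showWarnings = FALSE)

message("Control: free donor- and acceptor-labelled DNA only ...")
null_fit <- expt_fccs_bridging(dual_conc = 0, seed = 41L)
print(null_fit)

message("Bridged: 30% of donor-bearing particles are double-labelled complexes ...")
fit <- expt_fccs_bridging(dual_conc = 1.2, seed = 42L)
print(fit)

tab <- data.frame(
  condition = c("no_bridging", "bridged_30pct"),
  N_ad = c(null_fit$N_ad, fit$N_ad),
  Cad_um3 = c(null_fit$Cad, fit$Cad),
  dual_fraction = c(null_fit$dual_fraction, fit$dual_fraction),
  D_complex = c(null_fit$Dad, fit$Dad),
  D_free_donor = c(null_fit$Dd, fit$Dd))
write.table(tab, "results/fccs_bridging.tsv", sep = "\t", row.names = FALSE,
            quote = FALSE)
message(sprintf("  recovered dual fraction %.3f (true 0.30); D_complex %.1f < D_free %.1f um^2/s",
                fit$dual_fraction, fit$Dad, fit$Dd))
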