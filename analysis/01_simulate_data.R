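#!/usr/bin/env Rscript
# Generate one example of every synthetic input the pipeline consumes and
# write them under results/, so later stages can be rerun from files.
library(flucbridge)
dir.create("results", showWarnings = FALSE)

opt <- optical_config()
message("Simulating a 10-s single-species photon stream (C = 6.65 um^-3, D = 50 um^2/s) ...")
st <- simulate_photon_stream(
  species_spec("donor_only", conc = 6.65, D = 50, eps = 1e4),
  opt, duration = 10, dt = suggest_dt(50), seed = 1)
message(sprintf("  %d photons; writing results/example_stream.tsv", length(st$times)))
write_photon_stream(st, "results/example_stream.tsv")

message("Simulating a 50-Mb contact map with planted 3x binding-site contacts ...")
spec <- contact_map_spec(length_bp = 50e6, resolution = 25e3, ps_exponent = -1,
                         anchor_bins = seq(200, 1800, by = 160),
                         anchor_fold = 3, depth = 4e7, seed = 2)
sim <- simulate_contact_map(spec)
write_contact_matrix(sim$matrix, "results/example_contacts.tsv")
write_bed(sim$anchors, "results/example_anchors.bed")
message(sprintf("  %d bins, %d anchors", nrow(sim$matrix$matrix), length(sim$anchors)))

message("Simulating an aggregation-kinetics trace (time constant 4.8 min) ...")
tr <- simulate_kinetic_trace(A = 1, R = 1 / 4.8, times = seq(0, 30, length.out = 100),
                             noise_sd = 0.01, seed = 3)
write.table(data.frame(t_min = tr$t, y = tr$y), "results/example_tht.tsv",
            sep = "\t", row.names = FALSE, quote = FALSE)
message("Done.")
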