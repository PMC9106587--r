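# independent brute-force ICE oracle: plain iteration on small matrices
brute_ice <- function(M, iters = 500) {
  b <- rep(1, nrow(M))
  for (i in seq_len(iters)) {
    s <- rowSums(M)
    d <- s / mean(s)
    M <- M / outer(d, d)
    b <- b * d
  }
  list(M = M, bias = b)
}

test_that("ICE equalizes marginals and matches the brute-force oracle", {
  cm <- contact_matrix(matrix(c(4, 1, 1, 1), 2, 2), resolution = 1e4)
  bal <- ice_normalize(cm, tol = 1e-10, max_iter = 2000)
  s <- rowSums(bal$matrix)
  expect_lt(sd(s) / mean(s), 1e-4)
  oracle <- brute_ice(matrix(c(4, 1, 1, 1), 2, 2))
  expect_equal(bal$matrix / sum(bal$matrix),
               oracle$M / sum(oracle$M), tolerance = 1e-6)
  # already-balanced symmetric marginals stay proportional to the input
  cm2 <- contact_matrix(matrix(c(2, 1, 1, 2), 2, 2), resolution = 1e4)
  bal2 <- ice_normalize(cm2)
  expect_equal(bal2$matrix / bal2$matrix[1, 1],
               cm2$matrix / cm2$matrix[1, 1], tolerance = 1e-4)
  expect_error(ice_normalize(contact_matrix(matrix(0, 3, 3),
                                            resolution = 1e4)),
               class = "empty_input")
})

test_that("ICE masks empty bins and is idempotent", {
  M <- matrix(c(5, 2, 0, 2, 3, 0, 0, 0, 0), 3, 3)
  cm <- contact_matrix(M, resolution = 1e4)
  bal <- ice_normalize(cm)
  expect_true(is.na(bal$bias[3]))
  expect_true(all(is.na(bal$matrix[3, ])))
  s <- rowSums(bal$matrix[1:2, 1:2])
  expect_lt(sd(s) / mean(s), 1e-4)
  # re-balancing a balanced matrix changes the bias only negligibly
  again <- ice_normalize(contact_matrix(bal$matrix[1:2, 1:2],
                                        resolution = 1e4))
  expect_lt(max(abs(again$bias / mean(again$bias) - 1)), 1e-5)
})

test_that("P(s) is flat for distance-independent maps and depth-invariant", {
  spec0 <- contact_map_spec(length_bp = 25e6, resolution = 25e3,
                            ps_exponent = 0, depth = 2e7, seed = 11)
  ps0 <- ps_curve(simulate_contact_map(spec0)$matrix)
  expect_lt(abs(ps_slope(ps0, c(1e5, 1e7))), 0.05)
  spec1 <- contact_map_spec(length_bp = 25e6, resolution = 25e3,
                            ps_exponent = -1, depth = 1e7, seed = 12)
  spec2 <- contact_map_spec(length_bp = 25e6, resolution = 25e3,
                            ps_exponent = -1, depth = 4e7, seed = 13)
  ps1 <- ps_curve(simulate_contact_map(spec1)$matrix)
  ps2 <- ps_curve(simulate_contact_map(spec2)$matrix)
  expect_equal(ps1$P, ps2$P, tolerance = 0.1)
  expect_error(ps_curve(contact_matrix(matrix(1, 1, 1), resolution = 1e4)),
               class = "invalid_argument")
})

test_that("planted checkerboard compartments are recovered by E1", {
  fx <- compartment_fixture()
  ce <- compartment_e1(fx$bal, orient_track = fx$comp)
  expect_gte(abs(cor(ce$e1, fx$comp, use = "complete.obs")), 0.9)
  expect_false(ce$compartment_free)
  # orientation flip negates E1
  ce2 <- compartment_e1(fx$bal, orient_track = -fx$comp)
  ok <- complete.cases(ce$e1, ce2$e1)
  expect_equal(ce2$e1[ok], -ce$e1[ok], tolerance = 1e-8)
  # saddle has enriched same-compartment corners
  sad <- ce$saddle
  expect_gt(mean(c(sad[1, 1], sad[10, 10]), na.rm = TRUE),
            mean(c(sad[1, 10], sad[10, 1]), na.rm = TRUE))
})

test_that("compartment-free maps are flagged", {
  spec <- contact_map_spec(length_bp = 20e6, resolution = 20e3,
                           ps_exponent = 0, depth = 2e7, seed = 16)
  bal <- ice_normalize(simulate_contact_map(spec)$matrix)
  ce <- compartment_e1(bal, orient_track = rep(c(1, -1), 500))
  expect_true(ce$compartment_free)
})

test_that("insulation boundaries recover planted domain borders", {
  spec <- contact_map_spec(length_bp = 20e6, resolution = 20e3,
                           ps_exponent = -1, tad_boundaries = c(300, 500, 700),
                           tad_fold = 2, depth = 3e7, seed = 17)
  bal <- ice_normalize(simulate_contact_map(spec)$matrix)
  res <- insulation_tads(bal)
  bnd <- (GenomicRanges::start(res$boundaries) - 1) / 20e3 + 1
  expect_equal(length(bnd), 3)
  expect_true(all(abs(bnd - c(300, 500, 700)) <= 1))
  expect_gt(res$aggregate_tad_strength, 1)
  # two blocks sharing one boundary
  spec1 <- contact_map_spec(length_bp = 16e6, resolution = 20e3,
                            ps_exponent = -1, tad_boundaries = 400,
                            tad_fold = 2, depth = 3e7, seed = 18)
  res1 <- insulation_tads(ice_normalize(simulate_contact_map(spec1)$matrix))
  b1 <- (GenomicRanges::start(res1$boundaries) - 1) / 20e3 + 1
  expect_equal(length(b1), 1)
  expect_lte(abs(b1 - 400), 1)
})

test_that("uniform maps yield no boundaries and contrast orders strength", {
  spec0 <- contact_map_spec(length_bp = 16e6, resolution = 20e3,
                            ps_exponent = -1, depth = 3e7, seed = 19)
  res0 <- insulation_tads(ice_normalize(simulate_contact_map(spec0)$matrix))
  expect_length(res0$boundaries, 0)
  strengths <- vapply(c(1.5, 2.5, 4), function(fold) {
    sp <- contact_map_spec(length_bp = 16e6, resolution = 20e3,
                           ps_exponent = -1, tad_boundaries = c(300, 500),
                           tad_fold = fold, depth = 3e7, seed = 20)
    insulation_tads(ice_normalize(simulate_contact_map(sp)$matrix))$aggregate_tad_strength
  }, numeric(1))
  expect_true(all(diff(strengths) > 0))
})

test_that("site classification follows the 1-bp overlap rule exactly", {
  a <- GenomicRanges::GRanges("chr1", IRanges::IRanges(
    start = c(101, 101, 500), end = c(200, 200, 600)))
  b <- GenomicRanges::GRanges("chr1", IRanges::IRanges(
    start = c(200, 201, 900), end = c(300, 300, 950)))
  # BED [100,200) vs [199,300): 1-bp overlap -> shared
  cls <- classify_sites(a[1], b[1])
  expect_length(cls$shared, 1)
  expect_length(cls$a_only, 0)
  # BED [100,200) vs [200,300): half-open adjacency -> not shared
  cls2 <- classify_sites(a[2], b[2])
  expect_length(cls2$shared, 0)
  expect_length(cls2$a_only, 1)
  # per-peak accounting partition
  cls3 <- classify_sites(a, b)
  expect_equal(length(cls3$a_only) + length(cls3$shared), length(a))
  expect_equal(length(cls3$b_only) + length(cls3$shared_b), length(b))
})

test_that("high-density clusters require the minimum peak count per bin", {
  peaks <- GenomicRanges::GRanges("chr1", IRanges::IRanges(
    start = c(1001, 5001, 20001, 60001), width = 200))
  bins <- cluster_filter(peaks, resolution = 25000, min_peaks = 2)
  expect_length(bins, 1)
  expect_equal(GenomicRanges::start(bins), 1)
  expect_equal(S4Vectors::mcols(bins)$n_peaks, 3L)
  expect_length(cluster_filter(peaks, min_peaks = 4), 0)
})

test_that("aggregation on a uniform matrix is flat with a 400-cell background", {
  n <- 600
  M <- matrix(50, n, n)
  cm <- contact_matrix(M, resolution = 25e3, balanced = TRUE)
  anchors <- GenomicRanges::GRanges("chrS", IRanges::IRanges(
    start = (c(100, 200, 300, 450) - 1) * 25e3 + 1, width = 25e3))
  ag <- pairwise_aggregate(cm, anchors, min_sep = 2e6)
  expect_true(all(ag$background_pair_count == 400))
  expect_equal(mean(ag$center_scores), 1, tolerance = 1e-12)
  expect_true(all(abs(ag$grid - 1) < 1e-12))
  expect_error(pairwise_aggregate(cm, anchors, min_sep = 4e8),
               class = "empty_result")
  off <- GenomicRanges::GRanges("chrS", IRanges::IRanges(start = 5, width = 11))
  expect_error(pairwise_aggregate(cm, off, min_sep = 2e6),
               class = "invalid_argument")
})

test_that("aggregation is invariant to global matrix scaling", {
  anchors <- seq(60, 740, by = 68)
  spec <- contact_map_spec(length_bp = 20e6, resolution = 25e3,
                           ps_exponent = 0, anchor_bins = anchors,
                           anchor_fold = 2, depth = 2e7, seed = 21)
  sim <- simulate_contact_map(spec)
  ag1 <- pairwise_aggregate(sim$matrix, sim$anchors, min_sep = 1e6)
  scaled <- contact_matrix(sim$matrix$matrix * 7.3, resolution = 25e3)
  ag2 <- pairwise_aggregate(scaled, sim$anchors, min_sep = 1e6)
  expect_equal(ag1$grid, ag2$grid, tolerance = 1e-12)
  expect_equal(ag1$center_scores, ag2$center_scores, tolerance = 1e-12)
})

test_that("pair fold changes and the paired centre-score comparison", {
  n <- 300
  M1 <- matrix(40, n, n)
  M2 <- matrix(20, n, n)
  # plant one tiny value so the half-min-positive pseudocount is negligible
  M1[1, 2] <- M1[2, 1] <- 1e-6
  M2[1, 2] <- M2[2, 1] <- 1e-6
  cm1 <- contact_matrix(M1, resolution = 25e3, balanced = TRUE)
  cm2 <- contact_matrix(M2, resolution = 25e3, balanced = TRUE)
  pairs <- data.frame(i = c(50, 80, 120), j = c(150, 220, 260))
  # identical matrices: zero fold change, degenerate paired t
  fc0 <- pair_fold_change(cm1, cm1, pairs)
  expect_true(all(fc0$log2fc == 0))
  cmp0 <- compare_center_scores(c(1, 2, 3), c(1, 2, 3))
  expect_true(cmp0$degenerate)
  # doubling: log2 fold change 1 in the pseudocount-negligible regime
  fc1 <- pair_fold_change(cm1, cm2, pairs)
  expect_equal(fc1$log2fc, rep(1, 3), tolerance = 1e-3)
  # constant difference across pairs is flagged degenerate
  cmp1 <- compare_center_scores(c(1, 2, 3), c(2, 3, 4))
  expect_true(cmp1$degenerate)
  # a real paired t-test matches the textbook formula
  s1 <- c(2.5, 3.1, 2.8, 3.4, 2.9)
  s2 <- c(2.1, 2.6, 2.9, 2.8, 2.5)
  cmp <- compare_center_scores(s1, s2)
  d <- s1 - s2
  t_manual <- mean(d) / (sd(d) / sqrt(length(d)))
  p_manual <- 2 * pt(-abs(t_manual), length(d) - 1)
  expect_equal(cmp$statistic, t_manual, tolerance = 1e-12)
  expect_equal(cmp$p_value, p_manual, tolerance = 1e-12)
  expect_equal(cmp$dof, 4)
  mism <- contact_matrix(matrix(1, 10, 10), resolution = 5e3)
  expect_error(pair_fold_change(cm1, mism, pairs),
               class = "invalid_argument")
})

test_that("BED round trip preserves intervals", {
  gr <- GenomicRanges::GRanges("chr2", IRanges::IRanges(
    start = c(1, 25001), width = 25000))
  path <- tempfile(fileext = ".bed")
  write_bed(gr, path)
  gr2 <- read_bed(path)
  expect_equal(GenomicRanges::start(gr2), GenomicRanges::start(gr))
  expect_equal(GenomicRanges::end(gr2), GenomicRanges::end(gr))
  unlink(path)
})
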