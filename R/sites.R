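#' Classify binding sites of two conditions by overlap
#'
#' Partitions two peak sets by the 1-bp overlap rule: two peaks overlap when
#' they share at least one base (half-open BED intervals sharing only an end
#' coordinate do not overlap). Every peak of `peaks_a` lands in exactly one
#' of `a_only` or `shared` (and analogously for `peaks_b`), so
#' `length(a_only) + length(shared) == length(peaks_a)`.
#'
#' @param peaks_a,peaks_b `GRanges` of peaks for the two conditions.
#' @return List with `a_only`, `shared` (the `peaks_a` members that overlap
#'   `peaks_b`), `b_only`, and `shared_b` (the `peaks_b` members that overlap
#'   `peaks_a`).
#' @export
classify_sites <- function(peaks_a, peaks_b) {
  validate_peaks(peaks_a); validate_peaks(peaks_b)
  hit_a <- IRanges::overlapsAny(peaks_a, peaks_b, minoverlap = 1L)
  hit_b <- IRanges::overlapsAny(peaks_b, peaks_a, minoverlap = 1L)
  list(a_only = peaks_a[!hit_a], shared = peaks_a[hit_a],
       b_only = peaks_b[!hit_b], shared_b = peaks_b[hit_b])
}

validate_peaks <- function(gr) {
  fb_check(methods::is(gr, "GRanges"), "peaks must be a GRanges",
           "invalid_input")
  fb_check(all(GenomicRanges::width(gr) >= 1),
           "malformed intervals (start >= end)", "invalid_input")
}

#' High-density binding-site clusters per genomic bin
#'
#' Returns the genome bins (of the given resolution) containing at least
#' `min_peaks` peak midpoints — the "high-density cluster" filter (default:
#' at least 2 peaks per 25-kb bin).
#'
#' @param peaks `GRanges` of peaks.
#' @param resolution Bin size (bp), default 25000.
#' @param min_peaks Minimum peak midpoints per bin, default 2.
#' @return `GRanges` of qualifying bins.
#' @export
cluster_filter <- function(peaks, resolution = 25000L, min_peaks = 2L) {
  validate_peaks(peaks)
  fb_check(resolution > 0 && min_peaks >= 1, "invalid resolution/min_peaks")
  if (!length(peaks)) return(GenomicRanges::GRanges())
  mid0 <- floor((GenomicRanges::start(peaks) - 1 +
                   GenomicRanges::end(peaks)) / 2) # 0-based midpoint
  bin <- floor(mid0 / resolution)
  key <- paste(as.character(GenomicRanges::seqnames(peaks)), bin)
  tab <- table(key)
  keep <- names(tab)[tab >= min_peaks]
  if (!length(keep)) return(GenomicRanges::GRanges())
  parts <- do.call(rbind, strsplit(keep, " "))
  b <- as.numeric(parts[, 2])
  gr <- GenomicRanges::GRanges(parts[, 1], IRanges::IRanges(
    start = b * resolution + 1, width = resolution))
  S4Vectors::mcols(gr)$n_peaks <- as.integer(tab[keep])
  sort(gr)
}

# map anchor GRanges (bin-aligned) to 1-based bin indices of a contact matrix
anchor_bin_indices <- function(cm, anchors) {
  fb_check(methods::is(anchors, "GRanges"), "anchors must be a GRanges")
  a <- anchors[as.character(GenomicRanges::seqnames(anchors)) == cm$chrom]
  if (!length(a)) return(integer(0))
  start0 <- GenomicRanges::start(a) - 1
  fb_check(all(start0 %% cm$resolution == 0) &&
             all(GenomicRanges::width(a) == cm$resolution),
           "anchors are not aligned to the matrix binning")
  sort(unique(as.integer(start0 / cm$resolution) + 1L))
}

#' Intra-chromosomal anchor pairs above a separation
#'
#' @param cm A [contact_matrix()].
#' @param anchors Bin-aligned `GRanges` of anchor bins.
#' @param min_sep Minimum pair separation (bp).
#' @param flank Flank kept clear of the chromosome ends (bp).
#' @return Data frame with bin indices `i < j`.
#' @export
anchor_pairs <- function(cm, anchors, min_sep, flank = 0) {
  bins <- anchor_bin_indices(cm, anchors)
  F <- as.integer(round(flank / cm$resolution))
  n <- nrow(cm$matrix)
  bins <- bins[bins - F >= 1 & bins + F <= n]
  if (length(bins) < 2) return(data.frame(i = integer(0), j = integer(0)))
  pr <- expand.grid(i = bins, j = bins)
  pr <- pr[pr$i < pr$j & (pr$j - pr$i) * cm$resolution >= min_sep, ]
  rownames(pr) <- NULL
  pr
}

#' Pairwise binding-site contact aggregation with sliding-window background
#'
#' For every intra-chromosomal anchor pair `(a, b)` separated by at least
#' `min_sep`, extracts the `(2F + 1) x (2F + 1)` contact submatrix centred on
#' `(a, b)` (with `F = flank/window` sliding windows of width `window` on
#' each side) from the balanced matrix. The background for a pair is the set
#' of `(2F)^2` bin-bin contacts formed by crossing the `2F` non-centre
#' sliding windows around `a` with those around `b` (400 at the defaults of
#' a 250-kb flank scanned in 25-kb windows); the pair's centre score is the
#' centre contact divided by the mean of its valid background, and the
#' aggregate grid is the mean over pairs of the submatrix divided by the
#' per-pair background mean (both pair orientations are accumulated, which
#' symmetrizes the grid and cancels the first-order distance-decay tilt).
#' Pairs with fewer than 50% valid (unmasked) background cells are excluded
#' and counted. The construction is observed/expected-like and therefore
#' invariant to global matrix scaling.
#'
#' @param cm A balanced [contact_matrix()].
#' @param anchors Bin-aligned `GRanges` of anchor bins (e.g. from
#'   [cluster_filter()] or [simulate_contact_map()]).
#' @param flank Scan extent on each side (bp), default 250 kb; must be a
#'   multiple of `window`.
#' @param window Sliding-window width (bp), default 25 kb; must equal the
#'   matrix resolution.
#' @param min_sep Minimum pair separation (bp). Default `2*flank + 3*window`,
#'   the closest separation at which the two background scans cannot overlap
#'   each other or the anchors.
#' @return An object of class `aggregate_grid`: `grid`
#'   (`(2F+1) x (2F+1)` mean normalized contacts, centre at `F + 1`),
#'   `n_pairs`, `center_scores`, `background_pair_count` (per pair),
#'   `n_excluded`, and `pairs` (the bin-index pairs used).
#' @export
pairwise_aggregate <- function(cm, anchors, flank = 250000, window = 25000,
                               min_sep = NULL) {
  fb_check(inherits(cm, "contact_matrix"), "cm must be a contact_matrix")
  fb_check(window == cm$resolution,
           "window must equal the matrix resolution")
  fb_check(flank %% window == 0, "flank must be a multiple of window")
  if (is.null(min_sep)) min_sep <- 2 * flank + 3 * window
  fb_check(min_sep > 2 * flank + window,
           "min_sep must exceed 2*flank + window (background overlap)")
  F <- as.integer(flank / window)
  pr <- anchor_pairs(cm, anchors, min_sep, flank = flank)
  if (!nrow(pr)) fb_stop("no eligible anchor pairs at this separation",
                         "empty_result")
  M <- cm$matrix
  sz <- 2L * F + 1L
  ctr <- F + 1L
  bg_mask <- base::matrix(TRUE, sz, sz)
  bg_mask[ctr, ] <- FALSE
  bg_mask[, ctr] <- FALSE

  grid_sum <- base::matrix(0, sz, sz)
  grid_n <- base::matrix(0, sz, sz)
  center_scores <- numeric(0)
  bg_counts <- integer(0)
  used <- logical(nrow(pr))
  for (p in seq_len(nrow(pr))) {
    i <- pr$i[p]; j <- pr$j[p]
    sub <- M[(i - F):(i + F), (j - F):(j + F)]
    bg <- sub[bg_mask]
    ok <- is.finite(bg)
    if (sum(ok) < 0.5 * length(bg) || !is.finite(sub[ctr, ctr])) next
    used[p] <- TRUE
    mbg <- mean(bg[ok])
    center_scores <- c(center_scores, sub[ctr, ctr] / mbg)
    bg_counts <- c(bg_counts, sum(ok))
    norm <- (sub + t(sub)) / (2 * mbg) # both orientations
    fin <- is.finite(norm)
    grid_sum[fin] <- grid_sum[fin] + norm[fin]
    grid_n <- grid_n + fin
  }
  if (!any(used)) fb_stop("all anchor pairs excluded by masking", "empty_result")
  structure(list(grid = grid_sum / grid_n, n_pairs = sum(used),
                 center_scores = center_scores,
                 background_pair_count = bg_counts,
                 n_excluded = sum(!used), flank = flank, window = window,
                 pairs = pr[used, , drop = FALSE]),
            class = "aggregate_grid")
}

#' @export
print.aggregate_grid <- function(x, ...) {
  F <- (nrow(x$grid) - 1) / 2
  cat(sprintf("aggregate_grid: %d pairs (%d excluded), centre score mean %.3g, flank %d x %d bins\n",
              x$n_pairs, x$n_excluded, mean(x$center_scores), 2 * F + 1, 2 * F + 1))
  invisible(x)
}

#' Per-pair contact fold changes and paired comparison of centre scores
#'
#' `pair_fold_change` computes per-anchor-pair `log2((m1 + pc)/(m2 + pc))`
#' of balanced contacts between two conditions on identical binning, with
#' pseudocount `pc` equal to half the smallest positive balanced value in
#' either matrix. `compare_center_scores` runs the two-sided paired t-test
#' on per-pair centre scores of two conditions; a constant difference
#' (degenerate variance) is flagged rather than raising.
#'
#' @param m1,m2 Balanced [contact_matrix()]s on identical binning.
#' @param pairs Data frame of bin-index pairs (`i`, `j`), e.g. from
#'   [anchor_pairs()] or an [pairwise_aggregate()] result's `pairs`.
#' @return `pair_fold_change`: data frame with `i`, `j`, `log2fc`.
#' @export
pair_fold_change <- function(m1, m2, pairs) {
  fb_check(inherits(m1, "contact_matrix") && inherits(m2, "contact_matrix"),
           "m1 and m2 must be contact_matrices")
  fb_check(m1$resolution == m2$resolution &&
             nrow(m1$matrix) == nrow(m2$matrix),
           "matrices must be on identical binning")
  v1 <- m1$matrix[cbind(pairs$i, pairs$j)]
  v2 <- m2$matrix[cbind(pairs$i, pairs$j)]
  pos <- c(m1$matrix[m1$matrix > 0], m2$matrix[m2$matrix > 0])
  pc <- min(pos, na.rm = TRUE) / 2
  data.frame(i = pairs$i, j = pairs$j, log2fc = log2((v1 + pc) / (v2 + pc)))
}

#' @rdname pair_fold_change
#' @param scores1,scores2 Per-pair centre scores of the two conditions
#'   (equal length, paired).
#' @export
compare_center_scores <- function(scores1, scores2) {
  fb_check(length(scores1) == length(scores2) && length(scores1) >= 2,
           "need paired score vectors")
  d <- scores1 - scores2
  if (sd(d) < .Machine$double.eps^0.5 * max(1, abs(mean(d)))) {
    return(list(statistic = NA_real_, dof = length(d) - 1, p_value = NA_real_,
                mean_difference = mean(d), degenerate = TRUE))
  }
  tt <- t.test(scores1, scores2, paired = TRUE)
  list(statistic = unname(tt$statistic), dof = unname(tt$parameter),
       p_value = tt$p.value, mean_difference = mean(d), degenerate = FALSE)
}

#' Read and write interval sets as BED3
#'
#' Thin wrappers over `rtracklayer` import/export, which handle the 0-based
#' half-open BED convention.
#'
#' @param gr A `GRanges`.
#' @param path File path (`.bed`).
#' @return The imported `GRanges` / `path` invisibly.
#' @export
write_bed <- function(gr, path) {
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' @rdname write_bed
#' @export
read_bed <- function(path) {
  rtracklayer::import(path, format = "BED")
}
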