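#' Binned chromatin contact matrix
#'
#' A symmetric nonnegative per-chromosome contact matrix at fixed binning
#' resolution, optionally ICE-balanced (then carrying per-bin bias weights;
#' masked bins are NA in both the bias and the balanced matrix).
#'
#' @param matrix Symmetric numeric matrix of contacts.
#' @param chrom Chromosome name.
#' @param resolution Bin size (bp).
#' @param balanced Logical: has ICE balancing been applied?
#' @param bias Per-bin multiplicative bias (NA on masked bins).
#' @return An object of class `contact_matrix`.
#' @export
contact_matrix <- function(matrix, chrom = "chrS", resolution, balanced = FALSE,
                           bias = NULL) {
  fb_check(is.matrix(matrix) && nrow(matrix) == ncol(matrix),
           "matrix must be square")
  fb_check(resolution > 0, "resolution must be > 0")
  fb_check(isTRUE(all.equal(matrix, t(matrix))), "matrix must be symmetric")
  fb_check(all(matrix >= 0 | is.na(matrix)), "contacts must be nonnegative")
  structure(list(chrom = chrom, resolution = resolution, matrix = matrix,
                 balanced = balanced, bias = bias),
            class = "contact_matrix")
}

#' @export
print.contact_matrix <- function(x, ...) {
  cat(sprintf("contact_matrix: %s, %d bins @ %g bp%s, total %.4g\n",
              x$chrom, nrow(x$matrix), x$resolution,
              if (x$balanced) " (balanced)" else "",
              sum(x$matrix, na.rm = TRUE)))
  invisible(x)
}

#' Specification of a synthetic contact map
#'
#' Ground-truth description for [simulate_contact_map()]: one chromosome,
#' power-law distance decay, +/-1 compartment labels per bin (checkerboard),
#' block domains delimited by boundary bins, anchor bins carrying planted
#' binding sites whose pairwise contacts are enriched `anchor_fold`-fold, and
#' a Poisson sampling depth.
#'
#' @param chrom Chromosome name.
#' @param length_bp Chromosome length (bp).
#' @param resolution Bin size (bp).
#' @param ps_exponent Decay exponent of contact probability vs distance
#'   (typically around -1).
#' @param compartment_track Optional +/-1 label per bin.
#' @param comp_fold Contact multiplier for same-compartment bin pairs.
#' @param tad_boundaries Optional boundary bin indices (1-based) delimiting
#'   block domains.
#' @param tad_fold Contact multiplier for same-domain bin pairs.
#' @param anchor_bins Optional bin indices (1-based) carrying binding sites.
#' @param anchor_fold Enrichment multiplier for anchor-anchor contacts (>= 1).
#' @param depth Total sampled read pairs.
#' @param seed Integer seed.
#' @return An object of class `contact_map_spec`.
#' @export
contact_map_spec <- function(chrom = "chrS", length_bp, resolution,
                             ps_exponent = -1,
                             compartment_track = NULL, comp_fold = 1.5,
                             tad_boundaries = integer(0), tad_fold = 2,
                             anchor_bins = integer(0), anchor_fold = 1,
                             depth = 2e6, seed = 1L) {
  fb_check(resolution > 0, "resolution must be > 0")
  fb_check(anchor_fold >= 1, "anchor_fold must be >= 1")
  fb_check(depth > 0, "depth must be > 0")
  n <- as.integer(ceiling(length_bp / resolution))
  fb_check(length(anchor_bins) == 0 ||
             (min(anchor_bins) >= 1 && max(anchor_bins) <= n),
           "anchor bins outside chromosome extent")
  if (!is.null(compartment_track)) {
    fb_check(length(compartment_track) == n &&
               all(compartment_track %in% c(-1, 1)),
             "compartment_track must be +/-1 per bin")
  }
  structure(list(chrom = chrom, length_bp = length_bp, resolution = resolution,
                 n_bins = n, ps_exponent = ps_exponent,
                 compartment_track = compartment_track, comp_fold = comp_fold,
                 tad_boundaries = sort(unique(as.integer(tad_boundaries))),
                 tad_fold = tad_fold,
                 anchor_bins = sort(unique(as.integer(anchor_bins))),
                 anchor_fold = anchor_fold, depth = depth, seed = seed),
            class = "contact_map_spec")
}

#' Simulate a contact map with planted structure
#'
#' Builds the expected contact surface
#' `E[i, j] = |i - j|^alpha x compartment x domain x anchor` (same-label
#' compartment pairs boosted `comp_fold`-fold, same-domain pairs
#' `tad_fold`-fold, anchor-anchor pairs `anchor_fold`-fold), scales it to the
#' requested sequencing depth, and Poisson-samples the upper triangle,
#' mirroring for exact symmetry. Anchors are returned as a
#' `GenomicRanges::GRanges` of their bins.
#'
#' @param spec A [contact_map_spec()].
#' @return List with `matrix` (a [contact_matrix()]) and `anchors`
#'   (a `GRanges`).
#' @export
simulate_contact_map <- function(spec) {
  fb_check(inherits(spec, "contact_map_spec"), "spec must be a contact_map_spec")
  n <- spec$n_bins
  d <- abs(outer(seq_len(n), seq_len(n), "-"))
  E <- pmax(d, 1)^spec$ps_exponent
  if (!is.null(spec$compartment_track)) {
    same <- outer(spec$compartment_track, spec$compartment_track, "==")
    E <- E * ifelse(same, spec$comp_fold, 1)
  }
  if (length(spec$tad_boundaries)) {
    block <- findInterval(seq_len(n), spec$tad_boundaries)
    same_block <- outer(block, block, "==")
    E <- E * ifelse(same_block, spec$tad_fold, 1)
  }
  if (length(spec$anchor_bins) && spec$anchor_fold > 1) {
    is_anchor <- seq_len(n) %in% spec$anchor_bins
    both <- outer(is_anchor, is_anchor, "&") & d > 0 # distinct sites only
    E <- E * ifelse(both, spec$anchor_fold, 1)
  }
  up <- upper.tri(E, diag = TRUE)
  E_up <- E[up] * spec$depth / sum(E[up])
  M <- base::matrix(0, n, n)
  M[up] <- withr::with_seed(spec$seed, rpois(length(E_up), E_up))
  M <- M + t(M) - diag(diag(M))
  cm <- contact_matrix(M, chrom = spec$chrom, resolution = spec$resolution)
  anchors <- if (length(spec$anchor_bins)) {
    GenomicRanges::GRanges(spec$chrom, IRanges::IRanges(
      start = (spec$anchor_bins - 1L) * spec$resolution + 1L,
      width = spec$resolution))
  } else GenomicRanges::GRanges()
  list(matrix = cm, anchors = anchors)
}

#' Iterative correction (ICE) of a contact matrix
#'
#' Removes multiplicative per-bin biases by iterative correction: bins with
#' zero coverage are masked, and the matrix is repeatedly divided by the
#' outer product of its (normalized) marginals until the coefficient of
#' variation of the unmasked row sums drops below `tol`. The balanced matrix
#' equals the raw matrix scaled by `1/(bias_i bias_j)`; masked bins are NA.
#' Re-running on a balanced result changes the bias by less than 1e-6
#' (idempotence).
#'
#' @param cm A raw [contact_matrix()].
#' @param max_iter Maximum iterations.
#' @param tol Convergence threshold on the marginal coefficient of variation.
#' @return A balanced [contact_matrix()] with `bias` and attribute
#'   `converged`.
#' @export
ice_normalize <- function(cm, max_iter = 200L, tol = 1e-4) {
  fb_check(inherits(cm, "contact_matrix"), "cm must be a contact_matrix")
  M0 <- cm$matrix
  if (all(M0 == 0, na.rm = TRUE)) fb_stop("all-zero matrix", "empty_input")
  n <- nrow(M0)
  mask <- rowSums(M0, na.rm = TRUE) > 0
  M <- M0[mask, mask, drop = FALSE]
  bias_sub <- rep(1, nrow(M))
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    s <- rowSums(M)
    cv <- sd(s) / mean(s)
    if (is.finite(cv) && cv < tol) { converged <- TRUE; break }
    delta <- s / mean(s)
    delta[delta == 0] <- 1
    M <- M / outer(delta, delta)
    bias_sub <- bias_sub * delta
  }
  # rescale so the balanced matrix preserves the total signal
  scale <- sum(M0[mask, mask]) / sum(M)
  M <- M * scale
  bias_sub <- bias_sub / sqrt(scale)
  bias <- rep(NA_real_, n)
  bias[mask] <- bias_sub
  out <- base::matrix(NA_real_, n, n)
  out[mask, mask] <- M
  res <- contact_matrix(out, chrom = cm$chrom, resolution = cm$resolution,
                        balanced = TRUE, bias = bias)
  attr(res, "converged") <- converged
  if (!converged) warning("ICE did not reach tolerance within max_iter")
  res
}

#' Contact probability versus genomic distance
#'
#' Mean contact per log-spaced distance band, normalized so that the band
#' probabilities, weighted by band width, integrate to 1. Depth-invariant by
#' construction on the normalized scale.
#'
#' @param cm A [contact_matrix()] (raw or balanced; reported as given).
#' @param bins_per_decade Log-spaced bands per decade of distance.
#' @return Data frame with `s` (band geometric mid, bp), `P`, and the band
#'   edges `s_lo`, `s_hi`.
#' @export
ps_curve <- function(cm, bins_per_decade = 8L) {
  fb_check(inherits(cm, "contact_matrix"), "cm must be a contact_matrix")
  n <- nrow(cm$matrix)
  fb_check(n >= 2, "matrix must have at least 2 bins")
  res <- cm$resolution
  d <- abs(outer(seq_len(n), seq_len(n), "-"))
  up <- upper.tri(d)
  dv <- d[up] * res
  mv <- cm$matrix[up]
  keep <- dv > 0 & is.finite(mv)
  dv <- dv[keep]; mv <- mv[keep]
  lo <- log10(res); hi <- log10(max(dv))
  le <- seq(lo, hi, by = 1 / bins_per_decade)
  if (tail(le, 1) < hi) le <- c(le, hi)
  edges <- 10^le
  # guard the band ends against 10^log10 round-off
  edges[1] <- edges[1] * (1 - 1e-9)
  edges[length(edges)] <- edges[length(edges)] * (1 + 1e-9)
  band <- findInterval(dv, edges, rightmost.closed = TRUE)
  mean_c <- tapply(mv, band, mean)
  idx <- as.integer(names(mean_c))
  s_lo <- edges[idx]; s_hi <- edges[idx + 1L]
  width <- s_hi - s_lo
  P <- as.numeric(mean_c)
  P <- P / sum(P * width)
  data.frame(s = sqrt(s_lo * s_hi), P = P, s_lo = s_lo, s_hi = s_hi)
}

#' Log-log slope of a P(s) curve over a distance range
#'
#' @param ps Data frame from [ps_curve()].
#' @param s_range Distance range (bp) over which to regress.
#' @return Fitted slope.
#' @export
ps_slope <- function(ps, s_range) {
  keep <- ps$s >= s_range[1] & ps$s <= s_range[2] & ps$P > 0
  fb_check(sum(keep) >= 3, "too few bands in range")
  coef(lm(log10(P) ~ log10(s), data = ps[keep, ]))[[2]]
}

# distance-expected per diagonal (mean over the chromosome at the working
# resolution, no smoothing) and the observed/expected matrix
oe_matrix <- function(M) {
  n <- nrow(M)
  d <- abs(outer(seq_len(n), seq_len(n), "-"))
  ok <- !is.na(M)
  sums <- rowsum(M[ok], d[ok])
  cnts <- rowsum(rep(1, sum(ok)), d[ok])
  expd <- rep(NA_real_, n)
  expd[as.integer(rownames(sums)) + 1L] <- sums / cnts
  OE <- M / base::matrix(expd[d + 1L], n, n)
  OE[!is.finite(OE)] <- NA
  OE
}

# 2D moving average with a w x w uniform kernel (NA-aware)
ma2d <- function(M, w) {
  if (w <= 1) return(M)
  n <- nrow(M)
  V <- M; V[is.na(V)] <- 0
  W <- (!is.na(M)) * 1
  k <- rep(1, w)
  smooth1 <- function(X) {
    X <- stats::filter(X, k, sides = 2) # filters each column
    t(unclass(stats::filter(t(unclass(X)), k, sides = 2)))
  }
  num <- smooth1(V); den <- smooth1(W)
  out <- num / den
  out[den == 0 | is.na(den)] <- NA
  out
}

#' Compartment eigenvector and saddle analysis
#'
#' Sliding-window observed/expected analysis of a balanced matrix: the
#' matrix is averaged over `window`-sized sliding windows stepping at the
#' binning resolution, divided by the per-distance expected, converted to a
#' Pearson correlation matrix, and decomposed; the first principal component
#' (E1) is sign-oriented to correlate positively with `orient_track` (a
#' planted label track for synthetic data, a GC-like reference for real
#' data). Positive E1 marks the active (A) compartment under that
#' orientation. The saddle is the mean observed/expected grid over E1
#' quantile bins (deciles by default), computed on unmasked bins.
#'
#' @param cm A balanced [contact_matrix()] with at least 50 usable bins.
#' @param window Sliding-window size (bp), default 100 kb.
#' @param orient_track Numeric per-bin orientation reference.
#' @param n_quantiles Saddle quantile bins.
#' @return List with `e1` (per-bin track), `var_explained`,
#'   `compartment_free` (TRUE when E1 explains < 10% of the variance),
#'   and `saddle` (quantile x quantile mean O/E matrix).
#' @export
compartment_e1 <- function(cm, window = 1e5, orient_track, n_quantiles = 10L) {
  fb_check(inherits(cm, "contact_matrix"), "cm must be a contact_matrix")
  M <- cm$matrix
  usable <- which(rowSums(M, na.rm = TRUE) > 0)
  fb_check(length(usable) >= 50, "need at least 50 usable bins")
  fb_check(length(orient_track) == nrow(M), "orient_track must match binning")
  w <- max(1L, as.integer(round(window / cm$resolution)))
  S <- ma2d(M, w)
  OE <- oe_matrix(S)
  # masked bins and bins whose smoothing window ran off the chromosome end
  # have all-NA rows; dropping them leaves a complete submatrix
  keep <- which(rowSums(is.finite(OE)) > 2)
  sub <- OE[keep, keep, drop = FALSE]
  C <- if (anyNA(sub)) {
    suppressWarnings(stats::cor(sub, use = "pairwise.complete.obs"))
  } else {
    suppressWarnings(stats::cor(sub))
  }
  C[!is.finite(C)] <- 0
  eg <- eigen(C, symmetric = TRUE)
  if (!any(is.finite(eg$values)) || eg$values[1] <= 0) {
    fb_stop("degenerate correlation matrix", "fit_failure")
  }
  e1_sub <- eg$vectors[, 1] * sqrt(eg$values[1])
  var_explained <- eg$values[1] / sum(pmax(eg$values, 0))
  ori <- suppressWarnings(stats::cor(e1_sub, orient_track[keep]))
  if (is.finite(ori) && ori < 0) e1_sub <- -e1_sub
  e1 <- rep(NA_real_, nrow(M))
  e1[keep] <- e1_sub

  # saddle over E1 quantiles of the (unsmoothed) O/E matrix
  OE_raw <- oe_matrix(M)
  qs <- quantile(e1, probs = seq(0, 1, length.out = n_quantiles + 1),
                 na.rm = TRUE)
  qbin <- cut(e1, breaks = unique(qs), include.lowest = TRUE, labels = FALSE)
  saddle <- base::matrix(NA_real_, n_quantiles, n_quantiles)
  for (a in seq_len(n_quantiles)) {
    ia <- which(qbin == a)
    if (!length(ia)) next
    for (b in seq_len(n_quantiles)) {
      ib <- which(qbin == b)
      if (length(ib)) saddle[a, b] <- mean(OE_raw[ia, ib], na.rm = TRUE)
    }
  }
  list(e1 = e1, var_explained = var_explained,
       compartment_free = var_explained < 0.1, saddle = saddle)
}

#' Insulation score, domain boundaries and aggregate domain strength
#'
#' Slides a `square` x `square` window along the diagonal: the insulation
#' score of bin `i` is the mean contact between the `square`-sized regions
#' immediately upstream and downstream, log2-normalized to the chromosome
#' mean. Boundaries are transition points of the insulation delta (mean over
#' `delta_window` upstream minus downstream): positions where the delta
#' crosses from positive to negative with prominence above
#' `min_prominence`. The aggregate domain strength is the mean within-domain
#' observed/expected divided by the mean between-adjacent-domain
#' observed/expected over the called domains.
#'
#' @param cm A balanced [contact_matrix()].
#' @param square Sliding square size (bp), default 1 Mb.
#' @param delta_window Window for the boundary delta (bp), default 200 kb.
#' @param min_prominence Minimum delta prominence for a boundary call.
#' @return List with `insulation` (per-bin track), `boundaries` (`GRanges`),
#'   `tads` (`GRanges` between consecutive boundaries) and
#'   `aggregate_tad_strength`.
#' @export
insulation_tads <- function(cm, square = 1e6, delta_window = 2e5,
                            min_prominence = 0.1) {
  fb_check(inherits(cm, "contact_matrix"), "cm must be a contact_matrix")
  M <- cm$matrix
  n <- nrow(M)
  res <- cm$resolution
  w <- as.integer(round(square / res))
  dw <- as.integer(round(delta_window / res))
  fb_check(n > 2 * w, "matrix span must exceed twice the square size")
  ins <- rep(NA_real_, n)
  for (i in (w + 1):(n - w)) {
    ins[i] <- mean(M[(i - w):(i - 1), (i + 1):(i + w)], na.rm = TRUE)
  }
  ins <- log2(ins / mean(ins, na.rm = TRUE))
  delta <- rep(NA_real_, n)
  for (i in (dw + 1):(n - dw)) {
    l <- mean(ins[(i - dw):(i - 1)], na.rm = TRUE)
    r <- mean(ins[(i + 1):(i + dw)], na.rm = TRUE)
    delta[i] <- l - r
  }
  bnd <- integer(0)
  for (i in which(!is.na(delta))[-1]) {
    if (is.na(delta[i - 1])) next
    if (delta[i - 1] > 0 && delta[i] <= 0) {
      lo <- max(1, i - dw); hi <- min(n, i + dw)
      prom <- max(delta[lo:i], na.rm = TRUE) - min(delta[i:hi], na.rm = TRUE)
      if (is.finite(prom) && prom >= min_prominence) {
        # place the boundary at the insulation minimum near the crossing
        seg <- (max(1, i - dw)):(min(n, i + dw))
        bnd <- c(bnd, seg[which.min(ins[seg])])
      }
    }
  }
  bnd <- sort(unique(bnd))
  boundaries <- if (length(bnd)) {
    GenomicRanges::GRanges(cm$chrom, IRanges::IRanges(
      start = (bnd - 1L) * res + 1L, width = res))
  } else GenomicRanges::GRanges()

  strength <- NA_real_
  if (length(bnd) >= 1) {
    OE <- oe_matrix(M)
    edges <- c(1L, bnd, n + 1L)
    blocks <- lapply(seq_len(length(edges) - 1),
                     function(k) edges[k]:(edges[k + 1] - 1L))
    within <- unlist(lapply(blocks, function(b) OE[b, b][upper.tri(OE[b, b])]))
    between <- unlist(lapply(seq_len(length(blocks) - 1), function(k) {
      as.vector(OE[blocks[[k]], blocks[[k + 1]]])
    }))
    strength <- mean(within, na.rm = TRUE) / mean(between, na.rm = TRUE)
  }
  tads <- if (length(bnd) >= 2) {
    GenomicRanges::GRanges(cm$chrom, IRanges::IRanges(
      start = (head(bnd, -1)) * res + 1L,
      end = (tail(bnd, -1)) * res))
  } else GenomicRanges::GRanges()
  list(insulation = ins, boundaries = boundaries, tads = tads,
       aggregate_tad_strength = strength)
}

#' Read and write contact matrices as triplet text
#'
#' Tab-delimited upper-triangle triplets `chrom  bin_i  bin_j  count`
#' (0-based bin indices) preceded by a sidecar header line
#' `#resolution=<bp>`. The round trip is lossless for integer counts.
#'
#' @param cm A [contact_matrix()].
#' @param path File path.
#' @param n_bins Number of bins for the reader (inferred from the largest
#'   index if missing).
#' @return The matrix (reader) or `path` invisibly (writer).
#' @export
write_contact_matrix <- function(cm, path) {
  M <- cm$matrix
  up <- which(upper.tri(M, diag = TRUE) & M != 0 & !is.na(M), arr.ind = TRUE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("#resolution=%d", as.integer(cm$resolution)), con)
  writeLines(sprintf("%s\t%d\t%d\t%.10g", cm$chrom, up[, 1] - 1L, up[, 2] - 1L,
                     M[up]), con)
  invisible(path)
}

#' @rdname write_contact_matrix
#' @export
read_contact_matrix <- function(path, n_bins = NULL) {
  first <- readLines(path, n = 1)
  fb_check(startsWith(first, "#resolution="),
           "missing #resolution= header", "invalid_input")
  res <- as.numeric(sub("#resolution=", "", first))
  df <- read.table(path, sep = "\t", comment.char = "#",
                   col.names = c("chrom", "bin_i", "bin_j", "count"))
  if (is.null(n_bins)) n_bins <- max(df$bin_i, df$bin_j) + 1L
  M <- base::matrix(0, n_bins, n_bins)
  M[cbind(df$bin_i + 1L, df$bin_j + 1L)] <- df$count
  M[cbind(df$bin_j + 1L, df$bin_i + 1L)] <- df$count
  contact_matrix(M, chrom = df$chrom[1], resolution = res)
}
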