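#' Photon-counting-histogram probability mass function
#'
#' Compound-Poisson PCH for a homogeneously distributed brightness: the
#' number of molecules in the observation volume is Poisson with mean
#' `N_bar`, and given `N` molecules the photon count in a bin is Poisson with
#' mean `N * eps`:
#' \deqn{\Pi(k; \bar N, \varepsilon) = \sum_{N=0}^{\infty}
#'   \frac{\bar N^N}{N!} e^{-\bar N}
#'   \frac{(N\varepsilon)^k}{k!} e^{-N\varepsilon}}
#' The infinite sum is truncated at `N_bar + 10 sqrt(N_bar) + 20`, bounding
#' the truncated tail mass below 1e-12. The distribution has mean
#' `N_bar * eps` and variance `N_bar * eps * (1 + eps)` (super-Poissonian for
#' any positive brightness).
#'
#' @param k Photon counts per bin (nonnegative integers, vectorized).
#' @param N_bar Mean occupancy of the observation volume.
#' @param eps Molecular brightness (counts per molecule per bin).
#' @return Probabilities, same length as `k`.
#' @examples
#' pch_pmf(0, N_bar = 1, eps = 0.5) # exp(-(1 - exp(-0.5)))
#' @export
pch_pmf <- function(k, N_bar, eps) {
  fb_check(all(k >= 0), "k must be nonnegative")
  fb_check(N_bar > 0, "N_bar must be > 0")
  fb_check(eps >= 0, "eps must be >= 0")
  nmax <- ceiling(N_bar + 10 * sqrt(N_bar) + 20)
  N <- 0:nmax
  pn <- dpois(N, N_bar)
  # rows: N, cols: k
  vapply(k, function(kk) sum(pn * dpois(kk, N * eps)), numeric(1))
}

new_pch_data <- function(counts_hist, bin_time, total_bins) {
  structure(list(bin_time = bin_time, counts_hist = counts_hist,
                 total_bins = total_bins),
            class = "pch_data")
}

# Poisson maximum likelihood of (N_bar, eps) on an observed count histogram,
# optionally restricted (and renormalized) to a k-range segment.
pch_ml_fit <- function(k, freq, k_range = NULL, start = NULL) {
  if (!is.null(k_range)) {
    keep <- k >= k_range[1] & k <= k_range[2]
    k <- k[keep]; freq <- freq[keep]
  }
  fb_check(sum(freq) > 0, "no observations in segment", "empty_input")
  if (is.null(start)) {
    mu <- sum(k * freq) / sum(freq)
    v <- sum(freq * (k - mu)^2) / sum(freq)
    eps0 <- max(v / max(mu, 1e-9) - 1, 0.05)
    start <- c(log(max(mu / eps0, 1e-3)), log(eps0))
  }
  nll <- function(p) {
    nb <- exp(p[1]); ep <- exp(p[2])
    pk <- pch_pmf(k, nb, ep)
    if (!is.null(k_range)) pk <- pk / sum(pch_pmf(k_range[1]:k_range[2], nb, ep))
    -sum(freq * log(pmax(pk, 1e-300)))
  }
  opt <- optim(start, nll, method = "Nelder-Mead",
               control = list(maxit = 500, reltol = 1e-10))
  if (opt$convergence != 0) fb_stop("PCH fit did not converge", "fit_failure")
  list(N_bar = exp(opt$par[1]), eps = exp(opt$par[2]), nll = opt$value)
}

pch_chisq <- function(k, freq, N_bar, eps) {
  n <- sum(freq)
  expct <- n * pch_pmf(k, N_bar, eps)
  # group the tail so every cell has expected count >= 5
  o <- freq; e <- expct
  while (length(e) > 2 && tail(e, 1) < 5) {
    ne <- length(e)
    e[ne - 1] <- e[ne - 1] + e[ne]; e <- e[-ne]
    o[ne - 1] <- o[ne - 1] + o[ne]; o <- o[-ne]
  }
  dof <- max(length(e) - 1 - 2, 1)
  sum((o - e)^2 / pmax(e, 1e-9)) / dof
}

#' Build and fit the photon-counting histogram of a stream
#'
#' Bins the photon stream (default 500 us bins, i.e. 2 kHz analysis),
#' histograms the per-bin counts, and fits the compound-Poisson PCH by
#' Poisson maximum likelihood. `model = "single"` fits one uniform-brightness
#' species. `model = "segmental"` additionally partitions the count range and
#' fits each segment separately, mirroring the analysis of long-tailed
#' histograms where no single brightness explains the data and each segment's
#' brightness serves as an oligomer-size proxy; the default breakpoint is the
#' smallest `k` at which the cumulative tail probability under the head fit
#' drops below `tail_p`.
#'
#' @param stream A [photon_stream()].
#' @param bin_time Counting bin (s), default `5e-4`.
#' @param model `"single"` or `"segmental"`.
#' @param channel,gate Optional photon selection before binning.
#' @param breakpoints Optional user-supplied segment breakpoints (count
#'   values); overrides the tail rule.
#' @param tail_p Tail-probability threshold for the automatic breakpoint.
#' @return A list with `data` (class `pch_data`) and `fit` (class `pch_fit`,
#'   with `N_bar`, `eps_counts`, `chisq_dof` and, for segmental fits, a
#'   `segments` data frame).
#' @export
build_and_fit_pch <- function(stream, bin_time = 5e-4,
                              model = c("single", "segmental"),
                              channel = NULL, gate = NULL,
                              breakpoints = NULL, tail_p = 1e-4) {
  model <- match.arg(model)
  fb_check(inherits(stream, "photon_stream"), "stream must be a photon_stream")
  fb_check(stream$duration / bin_time >= 1e4,
           "stream must cover at least 1e4 bins")
  times <- select_photons(stream, channel = channel, gate = gate)
  counts <- bin_photon_counts(times, stream$duration, bin_time)
  if (max(counts) == 0) fb_stop("all counting bins are empty", "empty_input")
  kmax <- max(counts)
  freq <- tabulate(counts + 1L, kmax + 1L)
  k <- 0:kmax
  dat <- new_pch_data(setNames(freq, k), bin_time, length(counts))

  head_fit <- pch_ml_fit(k, freq)
  fit <- list(N_bar = head_fit$N_bar, eps_counts = head_fit$eps,
              chisq_dof = pch_chisq(k, freq, head_fit$N_bar, head_fit$eps),
              segments = NULL)

  if (model == "segmental") {
    if (is.null(breakpoints)) {
      # smallest k whose tail probability under the head fit is < tail_p
      tailp <- 1 - cumsum(pch_pmf(k, head_fit$N_bar, head_fit$eps))
      kb <- k[which(tailp < tail_p)[1]]
      if (is.na(kb) || kb >= kmax) kb <- max(1L, kmax %/% 2L)
      breakpoints <- kb
    }
    edges <- sort(unique(c(0L, as.integer(breakpoints), kmax + 1L)))
    segs <- lapply(seq_len(length(edges) - 1), function(i) {
      kr <- c(edges[i], edges[i + 1] - 1L)
      if (sum(freq[k >= kr[1] & k <= kr[2]]) == 0) return(NULL)
      sf <- tryCatch(pch_ml_fit(k, freq, k_range = kr),
                     error = function(e) NULL)
      if (is.null(sf)) return(NULL)
      data.frame(k_lo = kr[1], k_hi = kr[2], N_bar = sf$N_bar, eps = sf$eps)
    })
    fit$segments <- do.call(rbind, segs)
  }
  list(data = dat, fit = structure(fit, class = "pch_fit"))
}

#' @export
print.pch_fit <- function(x, ...) {
  cat(sprintf("pch_fit: N_bar = %.4g, eps = %.4g counts/bin, chisq/dof = %.3g\n",
              x$N_bar, x$eps_counts, x$chisq_dof))
  if (!is.null(x$segments)) {
    cat("  segments:\n"); print(x$segments)
  }
  invisible(x)
}

#' Burst histogram in multiples of the average photon rate
#'
#' Bins the stream (default 20 ms bins, i.e. 50 Hz analysis) and histograms
#' the per-bin counts expressed as integer multiples of the average bin
#' count (rounded to nearest, ties half up). A uniform-brightness sample
#' concentrates at multiples 0-2; bright bursts from large oligomers populate
#' high multiples.
#'
#' @param stream A [photon_stream()].
#' @param bin_time Bin width (s), default 0.02.
#' @param channel,gate Optional photon selection.
#' @return An object of class `burst_histogram` with `bin_time`, `mean_rate`
#'   (counts/s) and `multiples_hist` (named vector: multiple -> frequency).
#' @export
burst_histogram <- function(stream, bin_time = 0.02, channel = NULL,
                            gate = NULL) {
  fb_check(inherits(stream, "photon_stream"), "stream must be a photon_stream")
  times <- select_photons(stream, channel = channel, gate = gate)
  if (length(times) == 0) fb_stop("empty photon stream", "empty_input")
  counts <- bin_photon_counts(times, stream$duration, bin_time)
  mu <- mean(counts)
  multiples <- floor(counts / mu + 0.5) # round half up
  tab <- table(multiples)
  structure(list(bin_time = bin_time, mean_rate = mu / bin_time,
                 multiples_hist = setNames(as.integer(tab), names(tab))),
            class = "burst_histogram")
}

#' @export
print.burst_histogram <- function(x, ...) {
  cat(sprintf("burst_histogram: %.4g counts/s mean rate, bin %.3g s\n",
              x$mean_rate, x$bin_time))
  print(x$multiples_hist)
  invisible(x)
}

#' Sample photon-count bins from the PCH model
#'
#' Draws `n` independent counting bins from the compound-Poisson PCH
#' (molecule number Poisson with mean `N_bar`, counts Poisson with mean
#' `N * eps`), for fit-recovery checks.
#'
#' @param n Number of bins.
#' @param N_bar Mean occupancy.
#' @param eps Brightness (counts/bin).
#' @param seed Integer seed.
#' @return Integer vector of counts.
#' @export
sample_pch <- function(n, N_bar, eps, seed = 1L) {
  withr::with_seed(seed, {
    N <- rpois(n, N_bar)
    rpois(n, N * eps)
  })
}
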