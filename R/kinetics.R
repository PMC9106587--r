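#' Kinetic trace container
#'
#' @param t Time points, sorted ascending (min or s; record in `units`).
#' @param y Signal values.
#' @param y_ref Optional reference-region signal (FRAP acquisition control).
#' @param units Units tag for the time axis.
#' @return An object of class `kinetic_trace`.
#' @export
kinetic_trace <- function(t, y, y_ref = NULL, units = "min") {
  fb_check(length(t) > 0, "times must be nonempty")
  fb_check(!is.unsorted(t), "times must be sorted ascending")
  fb_check(length(y) == length(t), "t and y must have equal length")
  if (!is.null(y_ref)) fb_check(length(y_ref) == length(t),
                                "y_ref must match t")
  structure(list(t = t, y = y, y_ref = y_ref, units = units),
            class = "kinetic_trace")
}

#' Simulate a noisy exponential kinetic trace
#'
#' Generates `y = A exp(R t)` plus Gaussian noise, the synthetic stand-in for
#' amyloid-aggregation reporter kinetics and fluorescence-recovery traces.
#' Reproducible under a fixed seed; the global RNG state is untouched.
#'
#' @param A Amplitude.
#' @param R Rate constant (1/time-unit of `times`).
#' @param times Time points, nonempty and sorted.
#' @param noise_sd Gaussian noise standard deviation (same units as `A`).
#' @param seed Integer seed.
#' @param units Time units tag.
#' @return A [kinetic_trace()].
#' @export
simulate_kinetic_trace <- function(A, R, times, noise_sd = 0, seed = 1L,
                                   units = "min") {
  fb_check(length(times) > 0, "times must be nonempty", "invalid_argument")
  fb_check(!is.unsorted(times), "times must be sorted")
  y <- A * exp(R * times)
  if (noise_sd > 0) {
    y <- y + withr::with_seed(seed, rnorm(length(times), 0, noise_sd))
  }
  kinetic_trace(times, y, units = units)
}

#' Fit a single-exponential model to a kinetic trace
#'
#' Two parameterizations:
#' * `mode = "growth"`: `y = A exp(R t)` (optionally plus a baseline
#'   offset), the aggregation-kinetics form; the reported `time_constant` is
#'   `1/|R|`.
#' * `mode = "frap_recovery"`: `y = F_inf - B exp(R t)` with `R < 0`, the
#'   decaying-deficit form of a post-bleach recovery on a normalized trace.
#'   `time_constant` is `-1/R`, the convention under which recovery
#'   half-times are quoted as `-1/R`; the actual half-time
#'   `ln(2) * (-1/R)` is reported alongside as `half_time`.
#'
#' Fitting is bounded Levenberg-Marquardt least squares with three jittered
#' restarts (fixed internal seed) to avoid local minima; uncertainties come
#' from the covariance of the converged fit.
#'
#' @param trace A [kinetic_trace()] with at least 5 points; FRAP traces
#'   should already be normalized (see [normalize_frap()]).
#' @param mode `"growth"` or `"frap_recovery"`.
#' @param offset_free For growth mode, also fit a baseline offset.
#' @return An object of class `exp_fit`: `A`, `R`, `time_constant`,
#'   `half_time`, `se_A`, `se_R`, `offset` (or `F_inf` for recovery mode),
#'   `sign_warning` (TRUE when `R` has the unexpected sign for the mode).
#' @export
fit_exponential <- function(trace, mode = c("growth", "frap_recovery"),
                            offset_free = FALSE) {
  mode <- match.arg(mode)
  fb_check(inherits(trace, "kinetic_trace"), "trace must be a kinetic_trace")
  fb_check(length(trace$t) >= 5, "need at least 5 points")
  t <- trace$t; y <- trace$y
  tspan <- max(diff(range(t)), .Machine$double.eps)

  fit_once <- function(start, formula, lower, upper) {
    tryCatch(minpack.lm::nlsLM(formula, data = data.frame(t = t, y = y),
                               start = start, lower = lower, upper = upper,
                               control = minpack.lm::nls.lm.control(maxiter = 300)),
             error = function(e) NULL)
  }
  multi_start <- function(start, ...) {
    jitters <- withr::with_seed(101L, replicate(3, stats::runif(length(start), 0.7, 1.3),
                                                simplify = FALSE))
    fits <- list(fit_once(start, ...))
    for (j in jitters) {
      s2 <- as.list(unlist(start) * j)
      fits <- c(fits, list(fit_once(s2, ...)))
    }
    fits <- Filter(Negate(is.null), fits)
    if (!length(fits)) fb_stop("exponential fit did not converge", "fit_failure")
    fits[[which.min(vapply(fits, stats::deviance, numeric(1)))]]
  }

  if (mode == "growth") {
    # log-linear start (positive part of the signal)
    pos <- y > 0
    R0 <- if (sum(pos) >= 2) coef(lm(log(y[pos]) ~ t[pos]))[[2]] else 1 / tspan
    A0 <- y[which.min(t)]
    if (A0 == 0) A0 <- mean(abs(y))
    if (offset_free) {
      fit <- multi_start(list(A = A0, R = R0, C0 = 0),
                         y ~ A * exp(R * t) + C0,
                         lower = c(-Inf, -Inf, -Inf), upper = c(Inf, Inf, Inf))
    } else {
      fit <- multi_start(list(A = A0, R = R0), y ~ A * exp(R * t),
                         lower = c(-Inf, -Inf), upper = c(Inf, Inf))
    }
    cf <- coef(fit)
    ses <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                    error = function(e) setNames(rep(NA_real_, length(cf)), names(cf)))
    out <- list(A = cf[["A"]], R = cf[["R"]],
                time_constant = 1 / abs(cf[["R"]]),
                half_time = log(2) / abs(cf[["R"]]),
                se_A = ses[["A"]], se_R = ses[["R"]],
                offset = if (offset_free) cf[["C0"]] else 0,
                F_inf = NA_real_,
                sign_warning = cf[["R"]] < 0, mode = mode)
  } else {
    Finf0 <- mean(tail(y, max(3, length(y) %/% 5)))
    B0 <- max(Finf0 - min(y), 1e-6)
    fit <- multi_start(list(F_inf = Finf0, B = B0, R = -3 / tspan),
                       y ~ F_inf - B * exp(R * t),
                       lower = c(-Inf, -Inf, -Inf), upper = c(Inf, Inf, -1e-12))
    cf <- coef(fit)
    ses <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                    error = function(e) setNames(rep(NA_real_, length(cf)), names(cf)))
    out <- list(A = cf[["B"]], R = cf[["R"]],
                time_constant = -1 / cf[["R"]],
                half_time = -log(2) / cf[["R"]],
                se_A = ses[["B"]], se_R = ses[["R"]],
                offset = NA_real_, F_inf = cf[["F_inf"]],
                se_F_inf = ses[["F_inf"]],
                sign_warning = cf[["R"]] > 0, mode = mode)
  }
  if (isTRUE(out$sign_warning)) {
    warning("fitted rate has the unexpected sign for mode '", mode, "'")
  }
  structure(out, class = "exp_fit")
}

#' @export
print.exp_fit <- function(x, ...) {
  cat(sprintf("exp_fit (%s): A = %.4g +/- %.2g, R = %.4g +/- %.2g\n",
              x$mode, x$A, x$se_A, x$R, x$se_R))
  cat(sprintf("  time constant 1/|R| = %.4g, half-time ln2/|R| = %.4g\n",
              x$time_constant, x$half_time))
  invisible(x)
}

#' Normalize a FRAP trace against a reference region
#'
#' Corrects a bleached-region trace for acquisition photobleaching by
#' dividing by the reference-region trace, then normalizes to the pre-bleach
#' mean: `F_norm(t) = (roi(t)/ref(t)) / mean_prebleach(roi/ref)`. The
#' pre-bleach mean of the output is exactly 1.
#'
#' @param roi Bleached-region [kinetic_trace()].
#' @param ref Reference-region trace on the identical time grid.
#' @param n_prebleach Number of pre-bleach frames (>= 1) at the start.
#' @return A normalized [kinetic_trace()].
#' @export
normalize_frap <- function(roi, ref, n_prebleach) {
  fb_check(inherits(roi, "kinetic_trace") && inherits(ref, "kinetic_trace"),
           "roi and ref must be kinetic_traces")
  fb_check(isTRUE(all.equal(roi$t, ref$t)), "time grids must be aligned")
  fb_check(n_prebleach >= 1, "need at least one pre-bleach frame")
  fb_check(n_prebleach < length(roi$t), "pre-bleach frames exceed the trace")
  fb_check(all(ref$y != 0), "reference trace contains zeros", "invalid_input")
  ratio <- roi$y / ref$y
  out <- ratio / mean(ratio[seq_len(n_prebleach)])
  kinetic_trace(roi$t, out, units = roi$units)
}

#' Soluble fraction from supernatant and pellet absorbances
#'
#' Fraction of protein remaining in the supernatant after centrifugation,
#' `100 * a_sup / (a_sup + a_pellet)` (percent of total). The alternative
#' supernatant-to-pellet ratio reading is available via
#' `denominator = "pellet"`.
#'
#' @param a_supernatant,a_pellet Absorbances (e.g. A280), nonnegative and not
#'   both zero.
#' @param denominator `"total"` (default) or `"pellet"`.
#' @return Percent solubility.
#' @examples
#' solubility_fraction(0.8, 0.2) # 80
#' @export
solubility_fraction <- function(a_supernatant, a_pellet,
                                denominator = c("total", "pellet")) {
  denominator <- match.arg(denominator)
  fb_check(a_supernatant >= 0 && a_pellet >= 0, "absorbances must be >= 0")
  if (a_supernatant == 0 && a_pellet == 0) {
    fb_stop("both absorbances are zero: fraction undefined", "undefined_ratio")
  }
  if (denominator == "total") 100 * a_supernatant / (a_supernatant + a_pellet)
  else 100 * a_supernatant / a_pellet
}

#' Linear calibration fits with prediction and inversion
#'
#' Ordinary least squares of a (possibly log10-transformed) response against
#' a standard variable: fluorescence intensity against known protein amounts,
#' or log molecular weight against chromatographic retention time.
#' `predict_calibration` maps x to the response scale;
#' `invert_calibration` maps an observed response back to x (e.g. retention
#' time to molecular weight, band intensity to amount). Prediction and
#' inversion are exact inverses on the fitted range.
#'
#' @param x Standard values (at least 2 distinct).
#' @param response Measured responses (positive when log-transformed).
#' @param transform `"identity"` or `"log10_response"`.
#' @return `fit_calibration` returns a `calibration_line` (slope, intercept,
#'   their standard errors, and the transform).
#' @export
fit_calibration <- function(x, response,
                            transform = c("identity", "log10_response")) {
  transform <- match.arg(transform)
  fb_check(length(x) >= 2 && length(x) == length(response),
           "need >= 2 (x, response) pairs")
  fb_check(length(unique(x)) >= 2, "x values are degenerate (all equal)")
  ty <- if (transform == "log10_response") {
    fb_check(all(response > 0), "log transform needs positive responses")
    log10(response)
  } else response
  fit <- lm(ty ~ x)
  cf <- coef(fit)
  # summary.lm warns on exactly collinear (perfect) calibration lines
  ses <- tryCatch(suppressWarnings(summary(fit)$coefficients[, "Std. Error"]),
                  error = function(e) c(NA_real_, NA_real_))
  structure(list(slope = cf[[2]], intercept = cf[[1]],
                 se_slope = unname(ses[2]), se_intercept = unname(ses[1]),
                 transform = transform),
            class = "calibration_line")
}

#' @rdname fit_calibration
#' @param line A `calibration_line`.
#' @export
predict_calibration <- function(line, x) {
  ty <- line$intercept + line$slope * x
  if (line$transform == "log10_response") 10^ty else ty
}

#' @rdname fit_calibration
#' @export
invert_calibration <- function(line, response) {
  ty <- if (line$transform == "log10_response") log10(response) else response
  (ty - line$intercept) / line$slope
}

#' Nuclear concentration from a measured amount per cell population
#'
#' Converts a calibrated molar amount measured over a cell population into a
#' per-nucleus concentration,
#' `amount / (n_cells * transfection_eff * nuclear_volume)`, using a nuclear
#' volume of 220 fl and, for transfected populations, the fraction of cells
#' actually expressing (default 80%).
#'
#' @param amount Amount of protein (mol).
#' @param n_cells Number of cells.
#' @param transfection_eff Expressing fraction in (0, 1]; use 1 for
#'   endogenous protein.
#' @param nuclear_volume Nuclear volume (litres), default 2.2e-13 (220 fl).
#' @return Concentration in mol/L.
#' @examples
#' nuclear_concentration(2.2e-16, 1e6, transfection_eff = 1) # 1 nM
#' @export
nuclear_concentration <- function(amount, n_cells, transfection_eff = 0.8,
                                  nuclear_volume = 2.2e-13) {
  fb_check(amount > 0 && n_cells > 0 && nuclear_volume > 0,
           "inputs must be positive")
  fb_check(transfection_eff > 0 && transfection_eff <= 1,
           "transfection_eff must be in (0, 1]")
  amount / (n_cells * transfection_eff * nuclear_volume)
}
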