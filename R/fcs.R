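#' Single-species 3D Gaussian FCS model
#'
#' Autocorrelation of one freely diffusing species in a 3D Gaussian
#' observation volume under one-photon excitation:
#' \deqn{G(\tau) = \frac{1}{\pi^{3/2} w_0^2 z_0 C}
#'   \frac{1}{(1 + 4D\tau/w_0^2)\sqrt{1 + 4D\tau/z_0^2}}}
#' The flow term of the full model is omitted by fixing the flow velocity at
#' zero (static solution measurements), where it evaluates to 1.
#'
#' @param tau Lag times (s), nonnegative.
#' @param C Concentration (particles/um^3).
#' @param D Diffusion coefficient (um^2/s).
#' @param w0,z0 Observation-volume waist and axial extent (um).
#' @return `G(tau)`, dimensionless.
#' @examples
#' fcs_model(0, C = 10, D = 430, w0 = 0.3, z0 = 1.5) # 1/(pi^1.5*0.09*1.5*10)
#' @export
fcs_model <- function(tau, C, D, w0, z0) {
  fb_check(all(tau >= 0), "tau must be nonnegative")
  fb_check(C > 0 && D > 0 && w0 > 0 && z0 > 0, "parameters must be positive")
  g0 <- 1 / (pi^1.5 * w0^2 * z0 * C)
  g0 / ((1 + 4 * D * tau / w0^2) * sqrt(1 + 4 * D * tau / z0^2))
}

new_fcs_fit <- function(C, D, w0, z0, se_C, se_D, residuals, converged,
                        G_inf = 0) {
  structure(list(C = C, D = D, V = 0, w0 = w0, z0 = z0,
                 se_C = se_C, se_D = se_D, G_inf = G_inf,
                 residuals = residuals, converged = converged),
            class = "fcs_fit")
}

#' @export
print.fcs_fit <- function(x, ...) {
  cat(sprintf("fcs_fit: C = %.4g +/- %.2g um^-3, D = %.4g +/- %.2g um^2/s (w0 = %.3g, z0 = %.3g)\n",
              x$C, x$se_C, x$D, x$se_D, x$w0, x$z0))
  invisible(x)
}

# weights: inverse variance with a floor of 1e-4 * G(0) on the s.e. to avoid
# zero-weight blow-ups on noiseless or block-degenerate lags
fit_weights <- function(curve, g0hat) {
  se <- curve$se
  se[!is.finite(se)] <- NA
  floor_se <- 1e-4 * abs(g0hat)
  se <- pmax(se, floor_se)
  se[is.na(se)] <- if (all(is.na(curve$se))) floor_se else
    max(se, na.rm = TRUE)
  1 / se^2
}

amplitude_guess <- function(curve) {
  stats::median(curve$G[seq_len(min(3L, length(curve$G)))])
}

#' Fit the single-species FCS model to a correlation curve
#'
#' Weighted least-squares fit of [fcs_model()] with the optics (`w0`, `z0`)
#' fixed from calibration, returning concentration and diffusion coefficient
#' with their uncertainties. Weights are the block-averaged per-lag standard
#' errors with a floor of `1e-4 * G(0)`.
#'
#' A small additive infinity offset `G_inf` is fitted alongside by default:
#' finite closed-volume acquisitions (and simulations in a periodic box with
#' a fixed particle number) leave a baseline of order `-1/N_total` on the
#' curve, and absorbing it keeps `C` and `D` unbiased. The fit is two-pass:
#' after an initial full-range fit, the lag window is trimmed to
#' `fit_window` lateral diffusion times (`tau <= fit_window * w0^2/(4 D)`),
#' the region where the diffusion model carries information and any
#' finite-volume baseline is effectively constant, and the fit is repeated.
#'
#' @param curve A [correlation_curve()] with at least 10 lags spanning at
#'   least two decades.
#' @param optics An [optical_config()] carrying the calibrated `w0`, `z0`.
#' @param init Optional list with starting values `C`, `D`.
#' @param fit_offset Fit the additive baseline `G_inf` (default TRUE).
#' @param fit_window Lag-window width of the second pass, in lateral
#'   diffusion times; `Inf` disables trimming.
#' @return An object of class `fcs_fit` with elements `C`, `D`, `V` (fixed 0),
#'   `w0`, `z0`, `se_C`, `se_D`, `G_inf`, `residuals`, `converged`.
#' @export
fit_fcs <- function(curve, optics, init = NULL, fit_offset = TRUE,
                    fit_window = 20) {
  fb_check(inherits(curve, "correlation_curve"), "curve must be a correlation_curve")
  fb_check(length(curve$lags) >= 10, "need at least 10 lags")
  fb_check(max(curve$lags) / min(curve$lags) >= 100,
           "lags must span at least two decades")
  w0 <- optics$w0; z0 <- optics$z0
  g0hat <- amplitude_guess(curve)
  sehat <- stats::median(curve$se[is.finite(curve$se)])
  if (!is.finite(sehat)) sehat <- 0
  if (g0hat <= 0 || g0hat < 3 * sehat) {
    fb_stop("correlation amplitude indistinguishable from zero", "amplitude_degenerate")
  }
  if (is.null(init)) {
    C0 <- 1 / (pi^1.5 * w0^2 * z0 * g0hat)
    half <- curve$lags[which.min(abs(curve$G - g0hat / 2))]
    D0 <- w0^2 / (4 * half)
    init <- list(C = C0, D = D0)
  }
  run_fit <- function(keep, start) {
    df <- data.frame(tau = curve$lags[keep], G = curve$G[keep])
    wts <- fit_weights(correlation_curve(df$tau, df$G, curve$se[keep],
                                         kind = curve$kind), g0hat)
    if (fit_offset) {
      minpack.lm::nlsLM(G ~ fcs_model(tau, C, D, w0, z0) + Ginf, data = df,
                        start = c(start, list(Ginf = 0)),
                        lower = c(1e-9, 1e-9, -Inf), weights = wts,
                        control = minpack.lm::nls.lm.control(maxiter = 200))
    } else {
      minpack.lm::nlsLM(G ~ fcs_model(tau, C, D, w0, z0), data = df,
                        start = start,
                        lower = c(1e-9, 1e-9), weights = wts,
                        control = minpack.lm::nls.lm.control(maxiter = 200))
    }
  }
  fit <- tryCatch({
    all_lags <- rep(TRUE, length(curve$lags))
    f1 <- tryCatch(run_fit(all_lags, list(C = init$C, D = init$D)),
                   error = function(e)
                     run_fit(all_lags, list(C = 1.05 * init$C,
                                            D = 1.05 * init$D)))
    if (is.finite(fit_window)) {
      D1 <- coef(f1)[["D"]]
      keep <- curve$lags <= fit_window * w0^2 / (4 * D1)
      if (sum(keep) >= 10) {
        # a perturbed restart; an exact-solution start can abort the
        # zero-residual refit, in which case the full-range fit stands
        f2 <- tryCatch(run_fit(keep, list(C = 1.02 * coef(f1)[["C"]],
                                          D = 1.02 * D1)),
                       error = function(e) NULL)
        if (!is.null(f2)) f1 <- f2
      }
    }
    f1
  }, error = function(e) fb_stop(paste("FCS fit failed:", conditionMessage(e)),
                                 "fit_failure"))
  est <- coef(fit)
  ses <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                  error = function(e) setNames(rep(NA_real_, length(est)),
                                               names(est)))
  new_fcs_fit(est[["C"]], est[["D"]], w0, z0, ses[["C"]], ses[["D"]],
              residuals = as.numeric(stats::residuals(fit)), converged = TRUE,
              G_inf = if (fit_offset) est[["Ginf"]] else 0)
}

#' Calibrate the observation volume from a reference dye
#'
#' Fits the single-species FCS model to a calibration curve with the
#' diffusion coefficient fixed at the reference value (rhodamine 110:
#' 430 um^2/s), returning the beam waist `w0` (and `z0` through the fitted or
#' fixed shape ratio). Doubling `D_ref` on the same curve scales the returned
#' `w0` by `sqrt(2)`, the scaling law of the diffusion term.
#'
#' @param curve A [correlation_curve()] measured on a single-species
#'   calibration sample.
#' @param D_ref Reference diffusion coefficient (um^2/s), default 430.
#' @param shape_ratio Axial-to-lateral ratio `z0/w0`. If `NULL` it is fitted;
#'   otherwise fixed (default 5, typical for one-photon confocal volumes).
#' @param fit_window Lag-window width of the second pass, in lateral
#'   diffusion times (see [fit_fcs()]); `Inf` disables trimming.
#' @return An [optical_config()] with calibrated `w0`, `z0`.
#' @export
calibrate_optics <- function(curve, D_ref = 430, shape_ratio = 5,
                             fit_window = 20) {
  fb_check(is.numeric(D_ref) && D_ref > 0, "D_ref must be > 0")
  g0hat <- amplitude_guess(curve)
  fb_check(g0hat > 0, "calibration curve has nonpositive amplitude",
           "amplitude_degenerate")
  half <- curve$lags[which.min(abs(curve$G - g0hat / 2))]
  w00 <- sqrt(4 * D_ref * half)
  run_cal <- function(keep, w0_start) {
    df <- data.frame(tau = curve$lags[keep], G = curve$G[keep])
    wts <- fit_weights(correlation_curve(df$tau, df$G, curve$se[keep],
                                         kind = curve$kind), g0hat)
    if (is.null(shape_ratio)) {
      fit <- minpack.lm::nlsLM(
        G ~ fcs_model(tau, C, D_ref, w0, ratio * w0) + Ginf, data = df,
        start = list(C = 1 / (pi^1.5 * w0_start^3 * 5 * g0hat),
                     w0 = w0_start, ratio = 5, Ginf = 0),
        lower = c(1e-9, 1e-4, 1.0, -Inf), weights = wts)
      est <- coef(fit)
      optical_config(w0 = est[["w0"]], z0 = est[["ratio"]] * est[["w0"]])
    } else {
      fit <- minpack.lm::nlsLM(
        G ~ fcs_model(tau, C, D_ref, w0, shape_ratio * w0) + Ginf, data = df,
        start = list(C = 1 / (pi^1.5 * w0_start^3 * shape_ratio * g0hat),
                     w0 = w0_start, Ginf = 0),
        lower = c(1e-9, 1e-4, -Inf), weights = wts)
      est <- coef(fit)
      optical_config(w0 = est[["w0"]], z0 = shape_ratio * est[["w0"]])
    }
  }
  all_lags <- rep(TRUE, length(curve$lags))
  cal <- run_cal(all_lags, w00)
  if (is.finite(fit_window)) {
    keep <- curve$lags <= fit_window * cal$w0^2 / (4 * D_ref)
    if (sum(keep) >= 10) {
      cal2 <- tryCatch(run_cal(keep, 1.02 * cal$w0), error = function(e) NULL)
      if (!is.null(cal2)) cal <- cal2
    }
  }
  cal
}
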