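#' Solvent and temperature parameters for hydrodynamic sizing
#'
#' @param T Temperature (K). Default 295.15 K (21.5 C room temperature).
#' @param eta Solvent viscosity (Pa s). Default 9.55e-4, water at ~21.5 C;
#'   buffers differ, so this is configurable.
#' @param kB Boltzmann constant (J/K).
#' @return An object of class `hydro_params`.
#' @export
hydro_params <- function(T = 295.15, eta = 9.55e-4, kB = 1.380649e-23) {
  fb_check(T > 0, "T must be > 0")
  fb_check(eta > 0, "eta must be > 0")
  structure(list(T = T, eta = eta, kB = kB), class = "hydro_params")
}

#' Hydrodynamic radius from a diffusion coefficient
#'
#' Stokes-Einstein relation `Rh = kB T / (6 pi eta D)`, with `D` given in
#' um^2/s and the result in nm. Strictly decreasing in `D`.
#'
#' @param D Diffusion coefficient (um^2/s), positive.
#' @param params A [hydro_params()].
#' @return Hydrodynamic radius in nm.
#' @examples
#' stokes_einstein_rh(430) # ~0.526 nm, a free small dye
#' @export
stokes_einstein_rh <- function(D, params = hydro_params()) {
  fb_check(all(D > 0), "D must be > 0")
  D_si <- D * 1e-12 # um^2/s -> m^2/s
  rh_m <- params$kB * params$T / (6 * pi * params$eta * D_si)
  rh_m * 1e9
}

#' Empirical radius-residue scaling laws
#'
#' Power laws `Rh = A N^nu` (Rh in Angstrom, N residues) for compact folded
#' proteins and for chemically denatured chains. Defaults `A = 4.75`,
#' `nu = 0.29` (folded) and `A = 2.21`, `nu = 0.57` (denatured) follow the
#' standard empirical calibration for the two reference states; all four are
#' configurable.
#'
#' @param A_folded,nu_folded,A_denatured,nu_denatured Scaling coefficients.
#' @return An object of class `rh_scaling`.
#' @export
rh_scaling <- function(A_folded = 4.75, nu_folded = 0.29,
                       A_denatured = 2.21, nu_denatured = 0.57) {
  fb_check(all(c(A_folded, nu_folded, A_denatured, nu_denatured) > 0),
           "scaling coefficients must be positive")
  fb_check(nu_denatured > nu_folded,
           "denatured exponent must exceed the folded exponent")
  structure(list(A_folded = A_folded, nu_folded = nu_folded,
                 A_denatured = A_denatured, nu_denatured = nu_denatured),
            class = "rh_scaling")
}

scaling_for <- function(model, scaling) {
  if (model == "folded") c(scaling$A_folded, scaling$nu_folded)
  else c(scaling$A_denatured, scaling$nu_denatured)
}

#' Residue number from hydrodynamic radius, and its inverse
#'
#' `residues_from_rh` inverts the empirical scaling law,
#' `N = (Rh / A)^(1/nu)`; `rh_from_residues` evaluates it,
#' `Rh = A N^nu`. The two are exact inverses.
#'
#' @param Rh Hydrodynamic radius (Angstrom), positive.
#' @param N Residue count, >= 1.
#' @param model `"folded"` or `"denatured"`.
#' @param scaling An [rh_scaling()].
#' @return Residue count / radius in Angstrom.
#' @examples
#' rh_from_residues(100, "folded")    # 18.06 A
#' rh_from_residues(100, "denatured") # 30.51 A
#' @export
residues_from_rh <- function(Rh, model = c("folded", "denatured"),
                             scaling = rh_scaling()) {
  model <- match.arg(model)
  fb_check(all(Rh > 0), "Rh must be > 0")
  p <- scaling_for(model, scaling)
  (Rh / p[1])^(1 / p[2])
}

#' @rdname residues_from_rh
#' @export
rh_from_residues <- function(N, model = c("folded", "denatured"),
                             scaling = rh_scaling()) {
  model <- match.arg(model)
  fb_check(all(N >= 1), "N must be >= 1")
  p <- scaling_for(model, scaling)
  p[1] * N^p[2]
}

#' Classify a measured size against the monomer size boundary
#'
#' The plausible monomer sizes of an `n_residues_monomer`-residue chain span
#' `[Rh_folded(N), Rh_denatured(N)]`. A measured hydrodynamic radius within
#' that boundary (denatured bound as ceiling) is compatible with a monomer;
#' beyond it the species must be an assembly, and the fold-estimate range
#' brackets how many monomer equivalents it could contain under the two
#' scaling models.
#'
#' @param Rh_measured Measured hydrodynamic radius (Angstrom).
#' @param n_residues_monomer Residues in the monomer (e.g. 305 for the
#'   full-length transcription factor studied here).
#' @param scaling An [rh_scaling()].
#' @return List with `within_monomer_boundary` (logical),
#'   `boundary` (folded and denatured monomer radii, Angstrom) and
#'   `fold_estimate_range` (low, high multiple of the monomer residue count).
#' @export
classify_assembly <- function(Rh_measured, n_residues_monomer,
                              scaling = rh_scaling()) {
  fb_check(Rh_measured > 0 && n_residues_monomer >= 1, "inputs must be positive")
  lo <- rh_from_residues(n_residues_monomer, "folded", scaling)
  hi <- rh_from_residues(n_residues_monomer, "denatured", scaling)
  fold <- sort(c(residues_from_rh(Rh_measured, "folded", scaling),
                 residues_from_rh(Rh_measured, "denatured", scaling)) /
                 n_residues_monomer)
  list(within_monomer_boundary = Rh_measured <= hi,
       boundary = c(folded = lo, denatured = hi),
       fold_estimate_range = fold)
}
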