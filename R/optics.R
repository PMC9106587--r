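#' Confocal optics and acquisition configuration
#'
#' Describes the observation volume and excitation scheme of a confocal
#' fluorescence fluctuation experiment: a 3D Gaussian detection profile with
#' lateral waist `w0` and axial extent `z0`, pulsed interleaved excitation
#' (PIE) alternating two lasers, donor-to-acceptor-channel bleed-through and
#' acceptor direct excitation, and a uniform background count rate.
#'
#' @param w0 Lateral beam waist (micrometres). Must be positive.
#' @param z0 Axial beam extent (micrometres). Must be at least `w0`.
#' @param pie_period Excitation alternation period (seconds). The two lasers
#'   alternate on this timescale, so every photon is attributable to its
#'   excitation source (its "gate").
#' @param leak_frac Donor-to-acceptor-channel bleed-through fraction `l`.
#' @param direct_frac Acceptor direct-excitation fraction `d` (acceptor
#'   emission under donor excitation, relative to its brightness).
#' @param bg_rate Background count rate per detection channel (counts/s).
#'
#' @return An object of class `optical_config`.
#' @examples
#' optical_config(w0 = 0.3, z0 = 1.5)
#' @export
optical_config <- function(w0 = 0.3, z0 = 1.5, pie_period = 25e-9,
                           leak_frac = 0.03, direct_frac = 0.01,
                           bg_rate = 0) {
  fb_check(is.numeric(w0) && length(w0) == 1 && w0 > 0, "w0 must be > 0")
  fb_check(is.numeric(z0) && length(z0) == 1 && z0 >= w0, "z0 must be >= w0")
  fb_check(pie_period > 0, "pie_period must be > 0")
  fb_check(leak_frac >= 0 && leak_frac < 1, "leak_frac must be in [0, 1)")
  fb_check(direct_frac >= 0 && direct_frac < 1, "direct_frac must be in [0, 1)")
  fb_check(bg_rate >= 0, "bg_rate must be >= 0")
  structure(list(w0 = w0, z0 = z0, pie_period = pie_period,
                 leak_frac = leak_frac, direct_frac = direct_frac,
                 bg_rate = bg_rate),
            class = "optical_config")
}

#' @export
print.optical_config <- function(x, ...) {
  cat(sprintf("optical_config: w0 = %.3g um, z0 = %.3g um (ratio %.2f)\n",
              x$w0, x$z0, x$z0 / x$w0))
  cat(sprintf("  PIE period %.3g ns, leak %.3g, direct %.3g, bg %.3g cps\n",
              x$pie_period * 1e9, x$leak_frac, x$direct_frac, x$bg_rate))
  invisible(x)
}

#' Fluorescent species specification
#'
#' One diffusing species in a photon-stream simulation: its labelling class,
#' oligomer stoichiometry (brightness multiplier), particle number density,
#' diffusion coefficient, per-fluorophore peak brightness, and, for
#' dual-labelled (donor + acceptor) particles, the intramolecular FRET
#' efficiency that splits donor-excited emission between the two channels.
#'
#' @param label_class One of `"donor_only"`, `"acceptor_only"`, `"dual"`.
#' @param conc Particle number density (particles per cubic micrometre).
#' @param D Diffusion coefficient (um^2/s).
#' @param eps Per-fluorophore peak brightness (counts/s at the beam centre).
#' @param stoichiometry Number of fluorophores per particle (integer >= 1);
#'   an n-mer of singly labelled subunits is n times brighter than a monomer.
#' @param efret Intramolecular FRET efficiency in `[0, 1]`; only meaningful
#'   for `label_class = "dual"`.
#'
#' @return An object of class `species_spec`.
#' @examples
#' species_spec("donor_only", conc = 6.65, D = 50, eps = 1e4)
#' @export
species_spec <- function(label_class = c("donor_only", "acceptor_only", "dual"),
                         conc, D, eps, stoichiometry = 1L, efret = 0) {
  label_class <- match.arg(label_class)
  fb_check(stoichiometry >= 1, "stoichiometry must be >= 1")
  fb_check(conc >= 0, "conc must be >= 0")
  fb_check(D > 0, "D must be > 0")
  fb_check(eps >= 0, "eps must be >= 0")
  fb_check(efret >= 0 && efret <= 1, "efret must be in [0, 1]")
  structure(list(label_class = label_class, stoichiometry = stoichiometry,
                 conc = conc, D = D, eps = eps, efret = efret),
            class = "species_spec")
}

# integer codes used by the C++ simulator
species_class_code <- function(label_class) {
  match(label_class, c("donor_only", "acceptor_only", "dual")) - 1L
}
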