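# Shared fixtures, built once per session and cached. All synthetic inputs
# are generated by the package's own simulators under fixed seeds.
fb_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(fb_cache[[key]])) assign(key, force(expr), envir = fb_cache)
  get(key, envir = fb_cache)
}

default_optics <- function(bg_rate = 0) optical_config(bg_rate = bg_rate)

# a medium FCS stream reused across correlation/fit tests
fcs_stream <- function() cached("fcs_stream", {
  sp <- species_spec("donor_only", conc = 6.65, D = 50, eps = 1e4)
  simulate_photon_stream(sp, default_optics(), duration = 20,
                         dt = suggest_dt(50), seed = 101)
})

fcs_curve <- function() cached("fcs_curve", {
  compute_correlation(fcs_stream(), list(channel = "D", gate = "Dex"),
                      lag_range = c(2 * suggest_dt(50), 0.5))
})

compartment_fixture <- function() cached("compartment_fixture", {
  comp <- rep(rep(c(1, -1), each = 50), 10) # 1 Mb checkerboard at 20 kb
  spec <- contact_map_spec(length_bp = 20e6, resolution = 20e3,
                           ps_exponent = -1, compartment_track = comp,
                           comp_fold = 1.6, depth = 2e7, seed = 15)
  list(comp = comp, bal = ice_normalize(simulate_contact_map(spec)$matrix))
})
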