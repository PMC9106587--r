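Package: flucbridge
Title: Fluorescence Fluctuation Spectroscopy and Chromatin Contact Analysis of
    Transcription-Factor Self-Assembly
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and analysis pipeline for single-molecule fluorescence
    fluctuation spectroscopy of self-assembling transcription factors and for
    the chromatin contacts they mediate. Includes a Brownian photon-stream
    simulator with pulsed interleaved excitation, multi-tau and direct
    correlators with FCS/FCCS model fitting, photon-counting-histogram and
    burst analysis, single-molecule FRET gating, correction and histogram
    fitting, Stokes-Einstein hydrodynamic sizing with empirical residue-number
    scaling laws, exponential kinetics and calibration fits, and Hi-C style
    contact-matrix analytics (ICE balancing, contact-probability decay,
    compartment eigenvectors, insulation-score domains and pairwise
    binding-site contact aggregation with sliding-window background
    normalization).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
LinkingTo: Rcpp
Imports:
    Rcpp,
    minpack.lm,
    methods,
    withr,
    stats,
    utils,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
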