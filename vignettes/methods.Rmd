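---
title: "Models and methods: fluorescence fluctuation spectroscopy and chromatin contact analysis of a self-assembling transcription factor"
author: "flucbridge"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`flucbridge` implements, as one tested pipeline, the quantitative analyses
used to characterize a transcription factor that self-assembles at nanomolar
concentration and bridges DNA: single-molecule fluorescence fluctuation
spectroscopy (FCS, FCCS, photon-counting histograms, burst analysis, smFRET
with pulsed interleaved excitation), hydrodynamic sizing, exponential
kinetics and calibrations, and Hi-C-style contact-matrix analytics ending in
pairwise binding-site contact aggregation. Every stage can be exercised on
synthetic data generated by the package itself, with known ground truth, so
the whole pipeline is testable without any external data sets.

# The photon-stream simulator

## Model

Point emitters diffuse by Brownian steps of standard deviation
$\sqrt{2D\,\Delta t}$ per axis in a periodic box (default
$8w_0 \times 8w_0 \times 4z_0$). The confocal detection weight is the 3D
Gaussian
$$W(x,y,z) = \exp\!\left(-\frac{2(x^2+y^2)}{w_0^2} - \frac{2z^2}{z_0^2}\right),$$
and a particle of stoichiometry $n$ and per-fluorophore brightness
$\varepsilon$ (counts/s at the beam centre) emits photons as an
inhomogeneous Poisson process with rate $n\varepsilon W$. Photon times are
drawn by accumulating the intensity integral against per-pathway exponential
clocks and are jittered uniformly within their generating step, which
removes $\Delta t$-comb artifacts from the correlator. Under pulsed
interleaved excitation the two lasers alternate on the nanosecond scale, far
below the propagation step, so each photon is simply tagged with the
excitation gate of the pathway that produced it:

* donor-only species emit under the donor gate, with a bleed-through
  fraction $l$ (default 0.03) recorded in the acceptor channel;
* acceptor-only species emit under the acceptor gate and, at a direct
  excitation fraction $d$ (default 0.01) of their brightness, under the
  donor gate;
* dual-labelled species split donor-gate emission between the donor channel
  ($\propto (1-E)$) and the acceptor channel ($\propto E$) according to
  their FRET efficiency $E$, and their acceptor also emits under its own
  gate. This is the minimal PIE-consistent model.

The background is a uniform Poisson process per detection channel with its
gate split evenly, since it is not synchronized with either laser.

## Parameters and defaults

* `w0 = 0.3` µm, `z0 = 1.5` µm: a typical one-photon confocal volume
  (shape ratio 5); these are also the values that the optics calibration
  recovers from a simulated 430 µm²/s reference-dye measurement.
* `dt = 1e-5` s: at least 10× shorter than the lateral diffusion time
  $w_0^2/4D$ for $D$ up to ~220 µm²/s. `suggest_dt()` implements the rule
  $\Delta t = w_0^2/(40 D)$, clamped to $[2\times10^{-6}, 10^{-4}]$ s, so
  slow species do not waste steps and fast dyes (430 µm²/s) stay well
  resolved; the smoothing of the correlation by time jitter is confined to
  lags below $2\Delta t$, which the analysis excludes.
* Box $8w_0 \times 8w_0 \times 4z_0$: keeps the periodic-boundary bias of
  the correlation amplitude below ~2%.
* Particle numbers are `conc × box volume` with stochastic rounding, so the
  expected count is exact even for sparse species.
* Every simulation call owns one named xoshiro256++ generator (seeded by
  splitmix64 from the user seed, normals by a 128-layer ziggurat), so
  results are a pure function of the arguments and R's global RNG state is
  never touched.

## What the simulator does not model

No triplet/blinking photophysics, detector afterpulsing or dead time, and
no nanosecond lifetime structure within the interleaved excitation period
(the instrument response beyond the alternation period is intentionally
omitted). Passing tests therefore demonstrate correct recovery under ideal
photophysics; real data add photophysical and detector artifacts that the
fitting models here do not remove.

# Correlation analysis

`compute_correlation()` estimates
$G(\tau) = \langle \delta F_1(t)\,\delta F_2(t+\tau)\rangle /
(\langle F_1\rangle\langle F_2\rangle)$ on binned photon counts with the
symmetric normalization (head/tail means), the convention whose single
species zero-lag amplitude is $G(0) = 1/(\pi^{3/2} w_0^2 z_0 C)$. The
multi-tau ladder uses 16 linear lags per octave and coarsens the trace by 2
per octave; the brute-force `direct` scheme evaluates the identical lags on
the identical coarse binning by plain summation and is retained as the
estimator oracle (the two agree to floating point). Per-lag standard errors
come from block averaging over 10 contiguous blocks.

The FCS model is the one-species, one-photon 3D Gaussian form
$$G(\tau) = \frac{1}{\pi^{3/2} w_0^2 z_0 C}\,
\frac{1}{(1+4D\tau/w_0^2)\sqrt{1+4D\tau/z_0^2}},$$
with the flow term omitted because the measurements are static (zero flow
velocity), where it equals 1. Fits are weighted Levenberg–Marquardt with the
per-lag standard errors floored at $10^{-4}G(0)$.

Two numerical choices matter in practice:

* **Infinity offset.** A closed volume with a fixed particle number carries
  a correlation baseline of order $-1/N_{\rm total}$ out to the box-crossing
  time. `fit_fcs()` therefore fits an additive `G_inf` by default; without
  it, $D$ is biased high by ~20% at the simulated box size.
* **Fit window.** The baseline is constant only below the box-crossing
  time, which is a fixed multiple (~32×) of the lateral diffusion time at
  the default box. After a full-range first pass, the fit is repeated on
  lags $\tau \le 20\,w_0^2/(4D)$, where the diffusion model carries its
  information; this two-pass scheme removes the residual tail bias for any
  $D$.

`calibrate_optics()` fixes $D$ at the reference value and fits $w_0$ (with
the shape ratio fixed at 5 by default, or fitted); doubling the reference
$D$ scales the returned $w_0$ by $\sqrt 2$, as the model dictates.

# Cross-correlation (FCCS)

The two autocorrelations are modelled as two-component sums over the free
single-labelled species and the double-labelled (bridged) species, sharing
the double-labelled density $C_{ad}$ and diffusion coefficient $D_{ad}$;
the cross-correlation carries only the double-labelled species. All three
curves are fitted simultaneously (log-parameterized for positivity, with
per-curve infinity offsets). The effective volume follows the printed
convention $V_{\rm eff} = \pi^{3/2} w_0^2 z_0 / (2\sqrt 2)$ and the
cross-correlated particle number the printed formula
$$N_{ad} = \frac{G_x(0)}{2\sqrt 2\, G_a(0) G_d(0)}.$$
Note that combining the companion definitions
$C_{ad} = G_x(0)/(G_a(0)G_d(0)V_{\rm eff})$ and $N_{ad} = C_{ad}V_{\rm eff}$
algebraically gives $G_x(0)/(G_a(0)G_d(0))$, a factor $2\sqrt2$ larger; the
two conventions are mutually inconsistent, so the fit reports the printed
$N_{ad}$ and the algebraic alternative (`n_ad_alt`) side by side. When the
cross-amplitude is statistically consistent with zero the fit returns
$N_{ad}\approx 0$ with a `cross_null` flag rather than failing.

# Photon-counting histograms and bursts

The PCH for a homogeneously distributed brightness is the compound Poisson
$$\Pi(k;\bar N,\varepsilon) = \sum_{N\ge 0}
\frac{\bar N^N e^{-\bar N}}{N!}\,\frac{(N\varepsilon)^k e^{-N\varepsilon}}{k!},$$
with mean $\bar N\varepsilon$ and variance
$\bar N\varepsilon(1+\varepsilon)$. The $N$-sum is truncated at
$\bar N + 10\sqrt{\bar N} + 20$, bounding the truncated mass below
$10^{-12}$. Fitting is Poisson maximum likelihood over histogram cells
(correct small-count statistics), not least squares. The uniform-profile
form is the printed analysis model; counts binned from the 3D Gaussian-beam
simulation follow it only approximately, which is exactly the situation of
the real instrument, so goodness-of-fit assertions are made on data sampled
from the model itself. Segmental fits (for long-tailed histograms where no
single brightness fits) renormalize the pmf on each count segment; the
default breakpoint is the smallest count whose tail probability under the
head fit drops below $10^{-4}$ — the segmentation rule is not specified by
the source analysis, so it is exposed as a parameter.

Burst analysis bins at 50 Hz and histograms each bin's count as its integer
multiple of the average bin count (rounding half up). Uniform samples
concentrate at multiples 0–2; oligomer transits populate multiples around
10, the brightness-ratio regime of interest.

# smFRET

Photons are gated and binned at 500 µs into $I_D$ (donor channel, donor
gate), $I_A^{\rm raw}$ (acceptor channel, donor gate) and $I_{AA}$
(acceptor channel, acceptor gate). Burst selection keeps bins with
$I_D + I_A^{\rm raw}$ above mean + 3 sd (the "optimal signal" criterion is
not specified by the source analysis, so the threshold is a parameter).
Corrected efficiencies use
$$I_A = I_A^{\rm raw} - l\,I_D - d\,I_{AA},\qquad
E = \frac{I_A}{I_A + \gamma I_D},\ \gamma = 1,$$
with the direct-excitation correction referenced to $I_{AA}$ (the reference
signal is not stated by the source analysis; both coefficients are
configurable). Negative corrected intensities are retained and the
histogram domain extends to $-0.2$, preserving the shot-noise shape of the
zero peak. Gaussian components are fitted by bounded Levenberg–Marquardt
with multi-start over initial widths; means are initialized by histogram
mode-finding (ties to lowest $E$), or can be supplied when the expected
peak positions are known by design.

For the bridged-fraction titration (donor-only DNA plus a fraction $f$ of
dual-labelled, $E\approx0.15$ complexes), the two component shapes are
common to the whole series, so they are fitted once on the pooled histogram
and only the per-condition amplitudes are then fitted (a linear,
deterministic step). The per-condition non-zero-peak area is linear in $f$;
with 240-s acquisitions per condition the regression achieves
$R^2 \approx 0.99$. The titration uses a $12\times12\times24$ µm box so the
sparse bridged species is represented by tens of particles rather than a
quantized 0 or 1.

The denaturation profile extracts the dominant fitted peak per denaturant
concentration and compares a linear drift against a linear-plus-sigmoid
two-state model. The cooperativity metric is the maximum slope of the
sigmoidal step, $A/(4s)$, with a delta-method confidence interval; the
sigmoid is preferred only when it improves AIC by more than 10 (a
five-parameter nonlinear model gains a few AIC units on any noisy series by
overfitting, so decisive evidence is required). "Non-cooperative" then
corresponds to the linear model being preferred or the metric's interval
covering zero.

# Hydrodynamics

$R_h = k_B T / (6\pi\eta D)$ with defaults $T = 295.15$ K (21.5 °C room
temperature) and $\eta = 9.55\times10^{-4}$ Pa·s (water at that
temperature); both are configurable because buffers differ. Residue-number
estimates use the empirical power laws $R_h = A N^{\nu}$ with
$A = 4.75$ Å, $\nu = 0.29$ for folded and $A = 2.21$ Å, $\nu = 0.57$ for
denatured chains, the standard calibration for the two reference states
(configurable). Note the two laws cross near $N \approx 15$: the denatured
chain is the larger state for every chain long enough to be a protein, and
the monomer size boundary for a 305-residue chain spans the folded bound
(~25 Å) to the denatured bound (~57 Å). A measured radius above the
denatured bound cannot be a monomer; the fold-estimate range brackets the
assembly size under the two scaling models.

# Kinetics and calibrations

Aggregation kinetics are fitted as $y = Ae^{Rt}$ (time constant $1/|R|$),
optionally with a baseline offset (off by default, matching normalized
traces). FRAP recoveries are fitted as $y = F_\infty - Be^{Rt}$ with
$R < 0$, the decaying-deficit parameterization implied by quoting recovery
half-times from a single exponential; the reported `time_constant` is
$-1/R$, matching the convention under which such half-times are quoted,
and the actual half-time $\ln 2\,(-1/R)$ is reported alongside. Nonlinear
fits use bounded least squares with three jittered restarts under a fixed
internal seed. FRAP traces are first reference-corrected and normalized to
the pre-bleach mean, which cancels any common multiplicative acquisition
bleaching exactly.

Solubility is the supernatant fraction of total,
$100\,a_{\rm sup}/(a_{\rm sup}+a_{\rm pellet})$; the wording of
supernatant-versus-pellet readings is ambiguous between fraction-of-total
and ratio-to-pellet, so the alternative is available via an option.
Calibration lines are ordinary least squares on the (optionally log10)
response with exact prediction/inversion; nuclear concentrations divide the
calibrated amount by cells × expressing fraction (default 0.8) × nuclear
volume (default 220 fl).

# Contact-matrix analytics

The synthetic generator builds an expected surface
$|i-j|^{\alpha} \times$ compartment $\times$ domain $\times$ anchor factors
(same-compartment pairs boosted `comp_fold`, same-domain pairs `tad_fold`,
distinct anchor-anchor pairs `anchor_fold`; the `*_fold` sizes are package
choices since only the structures themselves are prescribed), scales it to
the sequencing depth and Poisson-samples the upper triangle, mirroring for
exact symmetry.

* **ICE**: iterative correction until the coefficient of variation of
  unmasked marginals falls below $10^{-4}$; zero-coverage bins are masked
  (NA), the balanced total is rescaled to the raw total, and re-balancing a
  balanced matrix is a no-op to within tolerance.
* **P(s)**: mean contact per log-spaced distance band (8 per decade),
  normalized so band probabilities weighted by band width integrate to 1;
  the normalized curve is depth-invariant.
* **Compartments**: the balanced 20-kb matrix is averaged over 100-kb
  sliding windows stepping at the bin size, divided by the per-distance
  expected (per-diagonal means, no smoothing), converted to a Pearson
  correlation matrix and eigendecomposed. E1 is sign-oriented to correlate
  positively with a supplied reference track (the planted labels for
  synthetic data; a GC-like track for real data). A map whose E1 explains
  less than 10% of the variance is flagged compartment-free. The saddle is
  the mean observed/expected over E1 deciles.
* **Insulation domains**: a 1-Mb square slides along the diagonal; the
  insulation score is the mean balanced contact between the upstream and
  downstream megabase, log2-normalized to the chromosome mean. Boundaries
  sit where the 200-kb left-minus-right delta crosses from positive to
  negative with prominence above 0.1, placed at the local insulation
  minimum. Aggregate domain strength is the mean within-domain
  observed/expected over the mean between-adjacent-domain value.
* **Binding-site aggregation**: for every intra-chromosomal anchor pair
  separated by at least `min_sep`, the $(2F+1)\times(2F+1)$ submatrix of
  25-kb windows (default flank 250 kb, $F = 10$) is extracted; the
  background is the $(2F)^2 = 400$ contacts of the non-centre windows of
  one anchor crossed with those of the other, the centre score is the
  centre contact over the mean valid background, and the grid accumulates
  both pair orientations, which cancels the distance-decay tilt to second
  order. Pairs with under 50% valid background cells are dropped and
  counted. The default `min_sep` of `2*flank + 3*window` is the closest
  separation at which the two background scans cannot overlap; the planted
  enrichment recovery is demonstrated at 10-Mb separations on a 100-Mb
  chromosome, where the local background is flat at the percent level.
  Condition comparisons use per-pair log2 ratios with a pseudocount of half
  the smallest positive balanced value, and a two-sided paired t-test on
  centre scores (constant differences are flagged degenerate rather than
  raising).

# Problem sizes used by the tests and the acceptance report

Unit tests run on seconds-long photon streams and 16–20 Mb synthetic
chromosomes. The end-to-end recovery checks use the full study-scale
conditions: fifteen 60-s FCS acquisitions over $D \in \{25, 100, 430\}$
µm²/s at 6.65 particles/µm³; two 60-s three-channel FCCS acquisitions;
240-s per-condition bridging titrations; and one deeply sampled
($10^9$ pairs) 100-Mb chromosome for the binding-site contact aggregation.
These sizes were chosen so that each recovery's sampling error sits well
inside the tolerance it is tested against.

# Known limitations

* The photon simulator's closed periodic box induces the finite-$N$
  correlation baseline discussed above; the fitting pipeline absorbs it,
  but simulated curves are not literally open-volume curves at lags beyond
  the box-crossing time.
* The uniform-profile PCH is an approximation for Gaussian-beam data (as in
  the original analysis); absolute brightness from stream-binned PCH fits
  is profile-convolved.
* Gaussian FRET peak shapes are phenomenological; no shot-noise-limited
  histogram deconvolution is attempted.
* The contact-map generator plants block/checkerboard structure with
  Poisson sampling only; it does not emulate read-level artifacts,
  mappability variation or translocations, so balancing is exercised
  against synthetic coverage bias only.
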