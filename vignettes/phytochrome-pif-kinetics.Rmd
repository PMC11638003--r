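---
title: "Modeling light-driven phytochrome-PIF interaction kinetics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling light-driven phytochrome-PIF interaction kinetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phypif)
```

## The reaction network and its assumptions

Plant phytochrome B interconverts between the dark-adapted Pr and the
light-activated Pfr conformer. Red light drives both directions — the
overlap of the Pr and Pfr absorbance spectra makes complete
photoconversion impossible — so constant 658-nm light establishes a
photostationary Pr:Pfr mixture (0.27:0.73 for the photosensory core
module) whose composition is intensity-independent while the cycling rate
through the two states grows linearly with intensity. Far-red (733-nm)
light drives essentially only the Pfr→Pr direction, and Pfr also decays
thermally back to Pr (dark reversion), slowly for the isolated core module
but strongly temperature-dependent.

The package models a receptor R interconverting between Pr and Pfr while
reversibly binding a PIF partner P in either state:

* photoconversion: `R ⇌ FR` with rates `k_p` (Pr→Pfr) and `k_q + k_rec`
  (Pfr→Pr), identical for free and complexed receptor;
* binding: `FR + P ⇌ FRP` with `k_aFR`, `k_dFR`; `R + P ⇌ RP` with
  `k_aR`, `k_dR`, where `k_aR = 0` by default because the Pr state binds
  PIFs only weakly — the Pr-state complex arises through photoconversion
  of the Pfr-state complex, not through association.

Five assumptions are built in: (i) photoconversion rates scale linearly
with intensity, with the `k_p/k_q` ratio pinned by the photostationary
Pfr:Pr ratio of the channel (0.73/0.27 for 658 nm); (ii) photochemistry is
unaffected by complexation; (iii) no receptor dimerization, Pr:Pfr
heterodimers, or Pr/Pfr substate heterogeneity — the homogeneous scheme
describes the data these methods target well, so more elaborate models are
deliberately not implemented; (iv) mass conservation of receptor and
partner; (v) well-mixed solution kinetics (no inner-filter or photon
transport effects).

The "attenuation" phenomenon falls out of the scheme: at high constant
red light, each receptor molecule shuttles rapidly between Pr and Pfr.
A complexed receptor visiting Pr can dissociate there (`k_dR` is fast,
~2.5 s⁻¹ for the P6A partner), and rebinding requires a comparatively slow
bimolecular association step. When cycling outpaces rebinding, the bound
fraction at steady state *decreases* with intensity even though the
Pr:Pfr ratio does not change.

## Units and parameter conventions

Concentrations are molar internally, time is seconds, light intensity is
mW cm⁻², temperature is kelvin internally with Celsius accepted at the
interfaces (`celsius_to_kelvin()`). Photon flux densities in
µE s⁻¹ m⁻² convert through `photon_flux_to_irradiance()` (0.0181 mW cm⁻²
per µE at 660 nm). Table-derived presets (`pif_preset()`) carry the
association rate constants already corrected for the partial Pfr
population, exactly as published.

Two red-light calibrations map intensity to photoconversion rates: the
default pins `k_p + k_q = 10 s⁻¹` at 69 mW cm⁻² (shutter-based
fluorescence measurement, giving `k_p_coeff ≈ 0.106 s⁻¹ per mW cm⁻²`);
an absorbance-derived alternative (5.2 s⁻¹ at the same intensity) can be
selected through `red_calibration()`. The two differ because the
instruments illuminate the cuvette differently; neither is privileged, so
the choice is explicit. The far-red coefficient defaults to
2.4 s⁻¹ / 42 mW cm⁻². Thermal reversion `k_rec` defaults to 0 — the core
module's dark-reversion time constant exceeds 200 h at 15 °C, negligible
on experiment timescales — but it is a first-class parameter: it carries
the temperature dependence of the photostationary state, and a finite
`k_rec` is what puts the *rising* flank of a dose–response curve at
nonzero intensity (with `k_rec = 0` the photostationary Pfr fraction, and
hence the binding plateau, is reached at infinitesimal light). The
instrument probe light (~0.05 mW cm⁻², inducing ~0.036 s⁻¹ drift) can be
represented as a weak constant red segment; it is off by default.

## Numerical choices

**Integration.** `simulate_kinetics()` integrates the five-species system
piecewise per illumination segment with `deSolve::lsoda` (stiff-capable;
the rate constants span six orders of magnitude), relative tolerance 1e-8
and an absolute tolerance scaled to 1e-10 of the largest total
concentration. Splitting at segment boundaries places the rate
discontinuities exactly at integrator restarts. Mass conservation holds to
better than 1e-6 relative along every trajectory (asserted in the tests).

**Photostationary state.** At fixed free-PIF concentration `p` the
receptor balance is linear; eliminating it turns the PIF balance into a
cubic polynomial in `p`. Rather than transcribing the printed coefficient
form — composite-sum notation of that kind is fragile to transcribe — the
implementation reconstructs the cubic exactly by evaluating
(residual × determinant) at four nodes and solving the Vandermonde
system, then takes the unique real root in `[0, P0]` via `polyroot` with a
bisection fallback (`uniroot`; the residual brackets a sign change on
`[0, P0]` by construction). With `k_aR = 0` the cubic degenerates to a
quadratic; the same machinery handles it without a special case, and the
two paths are cross-checked in the tests. Agreement with the ODE terminal
state to 1e-5 relative over randomized parameter draws is the correctness
oracle for both solvers.

**Estimators.** All nonlinear fits use Levenberg–Marquardt
(`minpack.lm::nlsLM`) with data-driven starting values; rate-like and
positivity-constrained parameters (`K_d`, `tau_D`, FCS and Arrhenius
scales) are fitted on the log scale. The consecutive
photoreversion-then-dissociation signal has a removable singularity at
`k_o = k_q`, evaluated by its analytic limit `(1 + k t) exp(-k t)`; the
amplitudes enter linearly, so the rate is first profiled on a log-spaced
grid before the full fit. The Arrhenius fit defaults to the
variance-stabilizing log-linear form (a direct nonlinear fit is
available); the two-state melt uses `ΔG = ΔH (1 − T/Tm)` with no heat
capacity term and temperature-linear baselines centered at the mean
scanned temperature for conditioning. Least squares is unweighted unless
the input carries per-point noise estimates, which then enter as
inverse-variance weights. Asymptotic standard errors come from the local
curvature; Monte-Carlo calibration tests keep the ratio of empirical
scatter to reported error inside [0.7, 1.3].

**Global fit.** `global_fit_interaction()` frees exactly two amplitudes
and four rate parameters (`k_p_coeff`, `k_aFR`, `k_dFR`, `k_dR`), pinning
`k_aR = 0` and the `k_p/k_q` split. Optimization is staged — Nelder–Mead
warm starts followed by Levenberg–Marquardt — because the
(`k_dR`, `k_dFR`, amplitude) combination forms a shallow curved valley in
the least-squares surface. A small multi-start along the `k_dR` axis plus
directed ±30× probes and NM/LM polish cycles track that valley reliably;
when the data carry no Pr-escape signature (truth `k_dR = 0`) the surface
is genuinely near-degenerate there and the fit correctly collapses to a
near-zero estimate.

**Dose–response features.** The attenuation onset is operationalized as
the lowest intensity above the peak at which the bound fraction has
dropped a configurable fraction (default 10%) below the peak,
interpolated on the log-intensity axis. The published "sets in around
0.1 mW cm⁻²" is a visual-onset statement; for parameter sets with shallow
attenuation (e.g. the PIF6 set at micromolar receptor) a smaller drop
threshold (3–5%) captures the same feature, and the tests use those
explicitly.

## The synthetic-data generator

`generate_dataset()` emulates each measurement type with the kinetic
structure of the corresponding experiment: association traces from the
full ODE forward model under a red pulse observed through the FRET map
(14% contrast, `F0 = 1`, `F1 = 0.86`); far-red dissociation traces from
the consecutive two-step model (`k_q = 2.4 s⁻¹`); photoconversion traces
as single exponentials; titrations from the single-site isotherm;
rate-versus-temperature tables from the Arrhenius law; melting curves from
the two-state model (midpoint 49.9 °C, `ΔH = 300 kJ mol⁻¹`, linear
baselines); FCS correlograms from the 3-D diffusion model (calibrations
γ = 9 / ω_r = 250 nm for the 510-nm channel, γ = 6 / ω_r = 304 nm for
640 nm). Defaults copy the experimental designs: 0.1-s fluorescence
cadence, 20 nM labeled partner, receptor series 500–2000 nM, 0.5-s
69 mW cm⁻² pulses, a 1/10/30/69 mW cm⁻² intensity ladder, 15–90 °C melts
at 1 °C steps. Noise is additive i.i.d. Gaussian scaled to the signal
span (the experiments report symmetric triplicate scatter and state no
heteroscedastic model); an occupancy-weighted option for FCS mimics
photon-counting statistics. Triplicate experiments are emulated by three
seeds per condition. The seed fully determines the output, truth
parameters travel only in metadata/sidecars, and the estimators never see
them.

What the generator does *not* emulate: instrument drift, photobleaching,
probe-light activation (beyond the optional constant segment),
correlated/heteroscedastic noise, receptor dimerization, and spectral
heterogeneity. Passing recovery tests therefore demonstrate estimator
correctness under the stated kinetic models, not robustness to every
artifact of real instruments.

One systematic effect *is* real and retained: after a saturating red
pulse, the first few hundred milliseconds of the decay contain a fast
transient from Pr-state complex release (`k_dR ≈ 2.5 s⁻¹`) superimposed on
the pseudo-first-order association. The recommended analysis — used in the
tests and the acceptance script — discards the first 0.6 s after light-off
before the monoexponential fit; the residual bias on the recovered
association rate constant is then a few percent (receptor depletion by the
20 nM partner and the slightly sub-photostationary Pfr population after a
0.5-s pulse), well inside the stochastic scatter of the design.

## Problem sizes

The test suite runs the analytic-versus-ODE oracle on 100 randomized
parameter draws, Monte-Carlo error calibrations with 60–500 replicates per
estimator, and three global fits over four 121-point traces each; the
acceptance script uses twelve 201-point association traces, one 81-point
dissociation trace, and one 76-point melting curve. These sizes were
chosen to keep every statistical check well-powered while remaining
desk-scale.

## Known limitations

* The Pr-state dissociation rate is only identifiable when it is slower
  than or comparable to the far-red photoreversion that precedes it; for
  `k_o` within ~5% of the fixed `k_q` the consecutive fit raises an
  identifiability flag, and such estimates systematically understate fast
  dissociation.
* With `k_rec = 0` and `k_aR = 0` the model retains a ~1% memory of the
  light-off Pr:Pfr partition in the final dark equilibrium, so post-light
  traces converge to intensity-independent levels only to that accuracy.
* The Smoluchowski encounter rate is reported in two unit modes
  (`as_printed`, the bare SI product conventionally quoted next to
  M⁻¹ s⁻¹ association constants, and `si_molar`, ×1000) because the two
  conventions differ by the liter–cubic-meter factor; comparisons of
  encounter and association rates in this literature use the former.
* Dose–response panel reproductions are qualitative: the exact simulated
  curves depend on concentration and dark-reversion values not published
  alongside the figures.
* No bootstrap or profile-likelihood intervals; errors are asymptotic.
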