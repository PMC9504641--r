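---
title: "Models and methods behind the fretforce pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind the fretforce pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fretforce)
```

`fretforce` chains four measurement modalities into one inference about a
biomolecular complex: how fast it dissociates, whether it forms a
ground-state complex in solution, how far apart a donor/acceptor pair sits
inside it, and which candidate structures are compatible with that distance
and energetically favourable. This vignette records the models, the
tunable parameters and their defaults, the numerical choices, and what the
synthetic-data generators do and do not emulate.

## Unbinding kinetics (Bell–Evans)

A single bond pulled at constant loading rate `r` (pN/s) ruptures most
probably at

$$F^* = \frac{k_B T}{x_\beta}\,\ln\frac{r\,x_\beta}{k_{off}\,k_B T},$$

where `k_off` (s⁻¹) is the zero-force dissociation rate and `x_β` (nm) the
distance to the transition state along the pulling direction. The full
first-rupture density, with $b = x_\beta/k_BT$,

$$p(F) = \frac{k_{off}}{r}\,e^{bF}\exp\!\Big[-\frac{k_{off}}{rb}\big(e^{bF}-1\big)\Big],$$

is implemented exactly (`rupture_force_pdf`), normalises to one, has its
mode at $F^*$ wherever that is positive, and inverts in closed form for
sampling (`sample_rupture_forces`). The density is evaluated on the log
scale so the survival factor tames the exponential overflow at large F.

Units are pN, nm and pN/s throughout, with $k_BT = 4.1145$ pN·nm at 298 K
(scaled linearly in temperature).

**Event detection.** `detect_unbinding_event` takes the largest force drop
along the retraction as the rupture and classifies it as specific only when
(i) the pre-jump rise is explained better, by residual sum of squares, by
the extensible tether model than by a straight line, and (ii) the rupture
separation falls inside 0.25–1.05 contour lengths. The tether is a freely
jointed chain (Langevin function, numerically inverted force–extension),
with defaults of 21 nm contour length and 0.7 nm Kuhn length appropriate
for a 3 kDa PEG linker. The window matters: at low force the freely jointed
chain is itself linear, so a linear adhesion ramp can mimic the tether's
residuals, but nonspecific adhesion detaches at near-zero separation and
fails the window. Both bounds are configurable.

**From events to parameters.** Specific rupture forces are binned (default
10 pN; 5 pN in high-statistics simulations), the main histogram peak is
fitted with a single Gaussian, and F\* per loading rate is regressed on
ln r (inverse-variance weighted when standard errors are given). The slope
gives `x_β = k_BT/slope`, the intercept gives
`k_off = exp(-intercept/slope)/slope`, with delta-method standard errors
and a log-scale t-interval for `k_off` (the residual variance rests on few
loading rates, so normal quantiles under-cover). A non-positive slope has
no single-barrier interpretation and is an error.

A caveat the tests quantify: the rupture-force density is left-skewed, so
the Gaussian-fitted peak sits ~1–2 pN below the analytic mode; the fitted
peak is within 10% of the mode and usable in the standard way, but
parameter-recovery studies perturb the exact F\* values directly (5%
multiplicative noise, five rates, 200 replicates), which is the cleaner
probe of the regression itself.

`k_on` cannot come from force spectroscopy; `affinity_constant` takes it as
an input (the motivating study's value, ~10⁴ M⁻¹s⁻¹, is the natural
default in examples) and reports K_A = k_on/k_off and τ = 1/k_off.

## Steady-state quenching (Stern–Volmer)

The linear model $F_0/F = 1 + K_{SV}[Q]$ is fitted with $F_0$ taken from
the measured zero-quencher point — not as a free intercept — because that
is what $F_0$ means; the fitted intercept is kept as a quality flag
(expected within 1 ± 0.05). Replicate standard deviations, when present,
propagate into ratio variances for weighting. Spectral corrections:
half-path inner-filter factor $10^{(A_{ex}+A_{em})/2}$ applied only above
0.15 OD at the excitation wavelength, blank subtraction clipped at zero,
and emission-peak location by quadratic interpolation (shift reporting).

Classification: static quenching requires an apparent
$k_q = K_{SV}/\tau_q$ at least two orders of magnitude above the diffusion
limit (default 10¹⁰ M⁻¹s⁻¹) *and* lifetime invariance (deviation below 4%);
dynamic quenching requires $k_q$ at or below the diffusion limit with
lifetimes tracking the intensity ratio; anything between is reported
ambiguous rather than forced. Note that a *dynamic* quencher at a large
K_SV would be unphysical (its collision rate would exceed diffusion), so
the synthetic dynamic scenario uses a diffusion-limited quencher
(k_q = 10⁹ M⁻¹s⁻¹, hence K_SV = k_q·τ₀ ≈ 5.4 M⁻¹) probed over its own
informative concentration range 0.05/K_SV – 2/K_SV.

## Time-resolved decays and FRET

TCSPC histograms are modelled as the multi-exponential
$I(t) = a_0 + \sum_i a_i e^{-t/\tau_i}$ convolved with the measured,
normalised instrument response. `fit_multiexp_reconvolution` performs
iteratively reconvolved least squares with Poisson weights
(variance = max(counts, 1) to avoid zero-count singularities), 1–3
components, a non-negative background, and a fitted sub-channel IRF timing
shift (linear interpolation) for real data whose excitation timing drifts;
simulation studies hold the shift at zero because the synthetic IRF has no
jitter. Start values come from a log-linear tail fit. Reduced χ² and the
weighted-residual trace are returned; on correctly specified synthetic
data χ²_red falls in roughly 0.85–1.2.

The mean lifetime is amplitude-weighted, $\sum a_i\tau_i/\sum a_i$,
matching the convention in which the numbers are reported downstream; the
intensity-weighted variant exists only behind an explicit option. FRET
efficiency uses the donor-lifetime-variation method
$E = 1 - \langle\tau_{DA}\rangle/\langle\tau_D\rangle$ (clamped into [0,1]
with a flag when inputs are unphysical), and the distance inversion
$D_{DA} = R_0((1-E)/E)^{1/6}$ refuses to run without a Förster radius:
R₀ is pair- and environment-specific and has no safe default. E = 0 or 1
is a hard error (infinite or zero distance).

## Structure screening and energetics

Candidate complex structures are read from PDB (via bio3d, after a
line-level validation pass that reports malformed coordinate fields by line
number). The donor site is the unweighted centroid of the nine tryptophan
indole-ring atoms; the acceptor site is the 5′-terminal phosphorus of the
nucleic-acid chain, falling back to O5′ for a phosphate-less first residue.
Coordinates are Å internally (PDB convention) and nm at every reported
interface.

Docking poses are grouped by single-linkage all-atom RMSD at a 0.1 nm
cutoff, computed **without** superposition because poses share the fixed
receptor frame (a superposition option exists, off by default); each
group's representative is its lowest-rank member, and whether "all atoms"
should instead be ligand-only is genuinely open — all-atom is the
documented default. The FRET screen keeps a model when its donor–acceptor
distance lies within one experimental standard deviation (half-width of
the window) of the experimental distance *plus* a 0.1 nm dye-linker
offset; with the motivating study's numbers (3.9 ± 0.2 nm + 0.1 nm) this
is the unique reading under which exactly the three published candidate
distances (3.8, 4.0, 4.2 nm) pass out of the 2.5–5.6 nm candidate range.

SASA is computed by Shrake–Rupley sampling: golden-spiral test points
(default 960/atom) on probe-inflated spheres (probe 1.4 Å), Bondi-type
element radii shipped as a configurable table. A test point lying exactly
on another atom's inflated sphere is occluded only by lower-index atoms, a
tie-break that makes exactly duplicated atoms count one surface while
being measure-zero for generic geometry. The nonpolar solvation term is
the linear model γ·SASA + β with γ = 2.27 kJ mol⁻¹ nm⁻² and
β = 3.84 kJ/mol.

Polar solvation and the entropic term are **consumed as inputs**, never
computed: they require a Poisson–Boltzmann solver and a quasi-harmonic
analysis of MD trajectories, which are out of scope.
`compose_binding_energy` accepts either per-species decompositions or
per-term deltas and sums
ΔG_B = ΔG_nonpol,solv + ΔE_MM + (−TΔS) + ΔG_pol,solv; both routes agree by
construction. Trajectory distance series are summarised by mean, SD and a
jump count, where a jump is a successive difference exceeding 3× the
median absolute successive difference whose new level persists for at
least 10 samples (windowed means on both sides must clear the same
threshold) — robust against lone noise spikes, by design.

## The synthetic-data generators

`synth_config` fixes one set of study conditions, used everywhere:
k_off = 0.44 s⁻¹, x_β = 0.73 nm at 298 K; five loading rates spanning
retraction velocities 50–4200 nm/s with a 10 pN/nm system spring constant
(0.5–42 nN/s, bracketing the 4.6 nN/s reference rate); 55% nonspecific
adhesion dropping to a 20% specific fraction under blocking; K_SV =
2.6×10⁴ M⁻¹ over 0–50 µM with 2% multiplicative intensity noise and five
replicates; donor decay components of 1.5 and 6.5 ns with amplitudes
0.224/0.776 (amplitude-weighted mean 5.38 ns, the short/long pair typical
of tryptophan in albumin), Gaussian IRF of 1 ns FWHM on 1024 channels of
0.05 ns, 10⁶ photons with 1% background; R₀ = 3.9 nm for FRET scenarios —
a synthetic choice made so efficiencies sit near 0.5 where the sixth-power
inversion is best conditioned, not a measured value; and 10 ns distance
trajectories at 0.1 ns steps around 3.8 nm with 0.1 nm fluctuations.

Noise models: additive Gaussian for forces, multiplicative Gaussian for
intensities, Poisson for photon counts. Every generator is a pure function
of (config, seed) and emits a ground-truth sidecar sufficient to score the
downstream estimators. FRET decays derive the acceptor-quenched lifetimes
by scaling every donor component by (1 − E) — the rate relation
k_T = (1/τ)(R₀/D)⁶ applied per component — so the amplitude-weighted mean
obeys the donor-lifetime-variation relation exactly.

What the generators do **not** emulate, and hence what green tests do not
show about real data: baseline drift and hydrodynamic artefacts in force
curves, multiple simultaneous tether ruptures, detector afterpulsing and
pile-up in TCSPC, dye photophysics and the orientation factor κ²
distribution behind R₀, real conformational ensembles behind the toy
complex geometry, and correlated noise in titrations.

## Problem sizes and reproducibility

The replicate studies the test suite runs are: 200 Bell–Evans refits of
noisy F\* values; 200 Stern–Volmer refits at the default titration design;
200 reconvolution fits of 10⁶-photon bi-exponential decays (1.5/6.5 ns,
amplitude ratio 1:2); and 200 + 200 labelled quenching scenarios for the
classifier. Detection-level checks use batches of 150–600 synthetic curves.
All randomness flows through explicit integer seeds; there is no hidden
RNG state (generators save and restore the global seed).

## Known limitations

Single-barrier Bell–Evans only (no piecewise multi-barrier regimes); no
cantilever calibration or 1/f-noise event disambiguation; linear
single-site Stern–Volmer only (no binding isotherms or anisotropy); donor
lifetime FRET only (no acceptor photophysics); no docking, MD propagation,
Poisson–Boltzmann solving or entropy estimation — those stages' outputs
are this package's inputs.
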