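---
title: "Methods: kinetic modeling and occupancy analysis in occupet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: kinetic modeling and occupancy analysis in occupet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(occupet)
```

`occupet` quantifies in vivo receptor occupancy from dynamic PET with an
image-derived input function. This vignette documents the model, the
conventions and the numerical choices, including the points where the
design was genuinely open and a decision had to be made.

## The kinetic model and its assumptions

The two-tissue compartment model (2TCM) describes exchange between
arterial parent plasma (`Cp`), a free/non-displaceable tissue pool (`C1`)
and a specifically bound pool (`C2`), at rates `K1` (mL·cm⁻³·min⁻¹) and
`k2, k3, k4` (min⁻¹), with zero initial conditions. The measured signal
adds fractional blood volume: `C_T = (1 − vB)(C1 + C2) + vB·C_wb`. The
model assumes instantaneous mixing within compartments, time-invariant
rate constants over the hour of scanning, and a spillover term carried by
whole blood — not plasma — since the vascular signal in a VOI is whole
blood. All times are minutes and all concentrations kBq/mL; rate
constants are then conventionally per-minute.

Binding potential `BP_ND = k3/k4` is the primary outcome: it is
proportional to available receptor density, so a drug occupying the
target lowers `k3` (association to free receptors) and with it `BP_ND`,
while `K1/k2` (non-displaceable volume) and `k4` are unaffected. This is
also exactly how the synthetic generator injects occupancy: `k3` is
scaled by `1 − RO/100`, nothing else. The derived volumes satisfy
`Vt = (K1/k2)(1 + BP)` and `Vs = Vt·BP/(1 + BP)` identically, which
doubles as an internal-consistency check on any reported table of group
means.

There is no usable reference region for this radioligand, so reference
tissue models (SRTM) and graphical methods are out of scope; the analysis
stands on the input function.

## Input function

The whole-blood curve from a left-ventricle VOI is modelled as a linear
rise from zero to the peak at `t_peak`, then a sum of three decaying
exponentials. The pre-peak shape is not identifiable from typical framing
and barely influences the late-time convolution; a linear rise with
`t_peak = 0.5` min is used as a neutral choice. The fit weights squared
residuals by frame duration and reports the reduced weighted chi-square
("chi"), the criterion used to select among deterministic multi-starts
over a fixed grid of rate triplets — two calls on the same data always
return the same model. Rates are reported sorted descending.

Parent plasma is obtained by two corrections applied multiplicatively:

* a fixed plasma:whole-blood count ratio, default 1.14;
* a parent fraction `pf(t) = plateau + (1 − plateau)·e^{−kt}` with
  `pf(0) = 1`, by default anchored so that `pf(5 min) = 0.16`. Measured
  (time, fraction) tables from a satellite cohort can be fitted instead
  (`fit_parent_fraction`).

The default plateau is 0: the anchor alone then fixes
`k = ln(1/0.16)/5 ≈ 0.367 min⁻¹`. A non-zero plateau is supported and
only changes the late tail of `Cp`.

## Numerics

The 2TCM solution is the bi-exponential impulse response with eigen-rates
`α₁,₂ = ½[(k2+k3+k4) ∓ √((k2+k3+k4)² − 4k2k4)]`, convolved with `Cp`.
Because `Cp` is piecewise exponential (linear-times-exponential before
the peak), the convolution integrals have closed forms; they are
evaluated with `expm1`-based branches so that near-coincident rates cost
no precision and large exponents cannot overflow. A repeated eigenvalue
(`k3 = 0` with `k2 = k4`) is handled by flooring the discriminant at
`(10⁻⁷(k2+k3+k4))²` — an infinitesimal symmetric eigenvalue split whose
relative effect (≈10⁻⁷) is far below every tolerance in use. Frame values
are the analytic curve averaged over each frame by 8-point Gauss–Legendre
quadrature, with frames straddling the input peak split there; for these
smooth integrands this is exact to machine precision, and the test suite
holds the forward model to within 0.1% of an adaptive ODE solution with
an integrated-state frame average (it agrees to ~10⁻⁸ in practice).

Fitting is bounded Levenberg–Marquardt (`minpack.lm`) on all five
parameters jointly, with box constraints `K1, k2, k3, k4 ∈ (0, 5]`,
`vB ∈ [0, 0.2]`. "Blood volume calculated for each animal" is read as
`vB` being free per animal rather than fixed from a separate measurement.
Weights are `w_i ∝ Δt_i` (frame durations normalized to sum 1) — the
plain frame-duration weighting; a count-variance alternative
(`Δt²/C`) is available behind `weighting = "duration_var"` but off by
default. Multi-start uses 8 deterministic, log-spaced starts (a two-level
half-fraction at log positions 0.3/0.7 of the start range); ties on the
weighted residual sum are broken by smaller `vB`, then lexicographic
parameter order. A solution pinned at a box constraint is returned with a
warning rather than rejected. The reduced chi-square and a
Gauss–Newton covariance (`chi·(JᵀWJ)⁻¹`) accompany every fit.

## Occupancy and uptake conventions

In a between-subjects design occupancy cannot be formed within animal;
each treated animal is compared against the **median** vehicle binding
potential of its genotype, and after all occupancies are computed, values
≤ 0 are replaced by the smallest strictly positive occupancy of the same
genotype. Two details are under-determined and resolved as follows: the
median over an even number of vehicle animals is the midpoint of the two
central values, and the clipping pool is the genotype across all of its
dose groups and drug arms — the same granularity as the median
convention. Vehicle animals contribute the baseline but are excluded from
occupancy reporting. A direct consequence worth knowing: with an odd
vehicle count, the median vehicle animal has raw occupancy exactly zero.

The Hill–Langmuir fit `RO(d) = RO_max·d^n/(d50^n + d^n)` uses bounded
least squares (`RO_max ∈ (0, 100]`, `d50 ∈ (0, 10·max dose]`,
`n ∈ (0, 5]`) from a small deterministic start grid; flat occupancy data
leave `d50` and `n` unidentified and are returned flagged
(`wide_uncertainty`) instead of failing.

%ID/g is the duration-weighted mean concentration over a 30–40 min
window — frames partially inside the window are weighted by their
overlap — divided by the injected activity, at unit tissue density
(1 g/mL). Whether the original computation used decay-corrected activity
is not documented; decay-corrected is the kinetic-modeling convention and
the default here (`decay_corrected = TRUE`), with the switch exposed.
All simulated and fitted curves are decay-corrected to injection time.

## Autoradiography

The unit of analysis is the ROI mean intensity; images and masks are
supported (`roi_mean`) but the primary input is the intensity table.
Three replicate slices per structure are averaged per animal, every
neural structure is divided by the same animal's muscle mean — making the
whole pipeline exactly invariant to per-animal film/exposure gain — and
structures are referenced to the overall structure mean because no
reference region exists. "Adjusted for dose and type" is implemented as
model-based adjusted means from the log-link regression (predictions
averaged over the observed genotype × dose grid); a degenerate design
(single cell) falls back to the unadjusted grand mean with a warning, in
which case the reference ratios average to exactly 1.

## Statistics

The test battery is rank-based and deliberately matches a
small-cohort design:

* **Exact Wilcoxon rank-sum**: midranks for ties; full enumeration of all
  `C(N, n₁)` group assignments (refused above a configurable combined
  `N = 20`); two-sided p is twice the smaller tail, capped at 1. The
  asymptotic mode uses the tie-corrected variance with a continuity
  correction — without the correction, exact and asymptotic p differ by
  up to ~0.03 at `N = 20`, with it by under 0.01.
* **van Elteren**: per-stratum rank sums combined with the locally
  optimal weights `1/(n_s + 1)`, standardized by the conditional mean and
  tie-corrected variance; with one stratum it reduces exactly to the
  Wilcoxon statistic. Strata containing a single group are dropped with a
  warning. A stratum-wise permutation p (default 10,000 shuffles, fixed
  logged seed) is available.
* **Linear-by-linear trend**: within-stratum statistic
  `Σ score·rank(value)` centered and scaled by its permutation moments,
  combined additively across strata. Scores default to the numeric doses
  {0, 1, 10, 30}; a rank-score option {1, 2, 3, 4} exists because the
  original score choice is not documented. Type-I error at the study's
  design size (16 animals, two strata) is 0.04–0.05 at nominal 0.05.
* **Log-link regression with clustering**: Gaussian family with log link
  (the family is switchable to Gamma; "log link" alone does not pin it
  down), IRLS started from the linear fit on the log scale, and
  animal-level cluster-robust (sandwich) standard errors — the simplest
  reading of "adjusted for clustering within animal", as opposed to
  random effects.
* No multiple-testing correction anywhere, by design.

## What the generator emulates — and what it does not

`generator_config()` encodes the study conditions: genotypes WT and KO at
oral doses {0, 1, 10, 30} mg/kg, 4–5 animals per cell plus an optional
4-animal reference-agonist arm at 1 mg/kg (fixed ≈17.6% occupancy), the
60-min framing protocol (60×3 s, 12×1 min, 3×5 min, 3×10 min), injected
activity ~N(7.77, 0.81) MBq, and body weight truncated to 15–45 g.
Defaults chosen where the conditions leave freedom, fixed once and not
tuned afterwards:

* **Baseline kinetics** `K1 = 0.75, k2 = 0.1, k3 = 0.051, k4 = 0.05,
  vB = 0.05`, giving vehicle `BP = 1.02`, `Vt = 15.15` — the observed
  baseline means. KO baseline equals WT (the observed 0.88 vs 1.02 is
  treated as within noise, consistent with no genotype difference in
  receptor density); a config switch allows genotype effects for power
  studies.
* **Hill defaults** `RO_max = 64.66, d50 = 1.856, n = 2.035`, the least-
  squares interpolation of the observed occupancy means (14.30% at 1,
  62.63% at 10, 64.44% at 30 mg/kg).
* **Blood curve**: amplitude fractions (0.82, 0.13, 0.05) at rates
  (4, 0.5, 0.03) min⁻¹, peak scaled at 814.98 kBq/mL per injected MBq —
  calibrated once so the noiseless vehicle whole-brain uptake is
  7.75 %ID/g.
* **Dispersion**: 10% log-normal CV on `K1..k4` per animal and 10% on the
  blood-curve peak. No per-animal values were published; 10% is a
  realistic inter-animal spread for healthy inbred mice and reproduces
  group SDs of the right order.
* **Noise**: zero-mean Gaussian per frame with SD
  `noise_scale·√(C/Δt)` and `noise_scale = 0.1`. The `1/Δt` variance
  scaling is exactly the structure frame-duration weighting assumes, so
  generator and estimator are consistent by construction. Real PET noise
  is Poisson-like and post-reconstruction correlated; Gaussian
  independent noise is a deliberate simplification.

Not emulated: scanner physics (randoms, scatter, partial volume, decay of
count-rate over the scan), anatomical atlases and VOI delineation, drug
pharmacokinetics (dose is mapped straight to equilibrium occupancy), and
any genotype effect on metabolism. Passing tests therefore demonstrate
the correctness of the estimators and conventions under the stated
statistical structure — not robustness to reconstruction artifacts or
model mismatch in real scans.

## Problem sizes and determinism

The test suite verifies the forward model against an adaptive ODE oracle
on 100 random parameter draws; recovery on 100 noisy vehicle animals
(median BP bias < 3%); the occupancy round-trip on 100 replicate
wild-type cohorts of 4 animals per dose (plateau recovered within 5
percentage points, monotone dose-response by sign test); trend-test
calibration on 2000 null simulations; and the autoradiography dose effect
on 100 replicate cohorts. The acceptance script repeats these
computations end to end, with every random draw derived from a single
`--seed`. All multi-starts and tie-breaks are deterministic, so identical
seeds give byte-identical pipeline output bundles.

## Known limitations

* The IDIF is taken as given (simulated or supplied); left-ventricle VOI
  extraction, dispersion and delay correction are out of scope.
* Truncated schedules (e.g. a 55-min scan) are legal everywhere — fitting
  simply uses the frames present — but no completeness correction is
  attempted.
* The exact Wilcoxon enumerator is O(C(N, n₁)) and intentionally capped;
  use the corrected asymptotic mode beyond ~20 observations.
* Occupancy clipping biases small true occupancies upward at small n —
  visible in simulated 1 mg/kg groups, and inherent to the convention,
  not to the implementation.
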