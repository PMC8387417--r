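# occupet

Receptor-occupancy analysis for dynamic small-animal PET.

`occupet` implements the full quantitative chain used to measure in vivo
target engagement of a CNS drug with a receptor-selective radioligand when
no reference region exists and arterial sampling is impractical — the
situation of sigma-1 receptor (S1R) imaging with [18F]FTC-146 in mice
dosed orally with an S1R agonist (blarcamesine, with PRE-084 as a
reference agonist). It is written for imaging scientists who want each
stage of such an analysis — input function, kinetics, occupancy,
statistics — as tested, reusable R functions rather than as a point-and-
click workflow.

## The model

Brain uptake follows the two-tissue compartment model (2TCM). With
arterial parent-plasma input `Cp(t)`, free/non-displaceable tissue
concentration `C1` and specifically bound concentration `C2`:

    dC1/dt = K1 Cp - (k2 + k3) C1 + k4 C2
    dC2/dt = k3 C1 - k4 C2
    C_T(t) = (1 - vB) (C1 + C2) + vB C_wb(t)

The measured PET signal `C_T` includes a fractional blood volume `vB`
carrying whole-blood activity `C_wb`. The micro-parameters give the
macro-parameters reported for each animal:

* binding potential `BP_ND = k3/k4` (proportional to available receptor
  density),
* total distribution volume `Vt = (K1/k2)(1 + k3/k4)`,
* volume of specific binding `Vs = Vt - K1/k2 = K1 k3/(k2 k4)`.

The input function is image-derived from the left ventricle: a linear
rise to the peak followed by three decaying exponentials, fitted by
frame-duration-weighted least squares with a reduced chi-square
criterion, then corrected to parent plasma with a fixed plasma:whole-
blood ratio (1.14) and a parent-fraction curve anchored at 16% intact
parent 5 minutes post-injection. The 2TCM prediction is computed by exact
analytic convolution of the bi-exponential impulse response with this
piecewise-exponential input — no ODE solver in the fitting loop.

Receptor occupancy at dose `d` uses the between-subjects convention

    RO(d) = (median BP(0) - BP(d)) / median BP(0) * 100

with the median vehicle baseline taken per genotype and any non-positive
occupancy replaced by the smallest positive occupancy of the same
genotype. Dose-response is summarized by the Hill–Langmuir curve
`RO(d) = RO_max d^n / (d50^n + d^n)`. Uptake is additionally quantified
as percent injected dose per gram over 30–40 min, and ex vivo
autoradiography intensities are quantified as triplicate ROI means
normalized to muscle (internal exposure control). Inference uses the
study's nonparametric battery: exact Wilcoxon rank-sum (full
enumeration), van Elteren's stratified rank-sum test, a stratified
linear-by-linear trend test, and log-link regression with animal-level
cluster-robust standard errors.

Because studies of this design rarely deposit per-animal curves, the
package ships a synthetic-cohort generator whose defaults emulate the
study conditions (two genotypes × 0/1/10/30 mg/kg, 4–5 animals per cell,
60-min framing `60×3 s, 12×1 min, 3×5 min, 3×10 min`, frame-duration-
scaled noise, occupancy acting on `k3` only), so every stage is testable
at desk scale against known ground truth.

## Worked example

Simulate a wild-type dose-escalation cohort, fit one animal, then compute
occupancy and its dose-response:

```r
library(occupet)

cfg    <- generator_config(n_per_group = 4, genotypes = "WT", pre084 = NULL)
cohort <- simulate_cohort(cfg, seed = 7)

id    <- cohort$metadata$animal_id[1]          # a vehicle animal
input <- fit_idif(cohort$blood_tacs[[id]], n_starts = 4)
fit   <- fit_2tcm(cohort$brain_tacs[[id]], input)
summary(fit)
#> Two-tissue compartment model fit
#>
#> Coefficients:
#>    Estimate Std. Error
#> K1 0.935550     0.0013
#> k2 0.089060     0.0005
#> k3 0.048340     0.0007
#> k4 0.048211     0.0004
#> vB 0.049082     0.0014
#>
#> BP_ND (k3/k4): 1.003   Vt: 21.04   Vs: 10.53 mL/cm3
#> Reduced weighted chi-square: 0.2959
```

A vehicle animal lands at `BP_ND` ≈ 1 — the receptor density baseline.
Fit every animal and convert binding potentials into percent occupancy:

```r
bp <- sapply(cohort$metadata$animal_id, function(a) {
  inp <- fit_idif(cohort$blood_tacs[[a]], n_starts = 2)
  fit_2tcm(cohort$brain_tacs[[a]], inp, n_starts = 4)$macros$bp_nd
})
occ <- receptor_occupancy(bp, cohort$metadata$genotype,
                          cohort$metadata$dose_mg_per_kg)
occ
#> Receptor occupancy (median vehicle baseline, positive clipping)
#> median BP(0): WT = 0.989
#>
#>  genotype drug dose  ro_mean    ro_sd n
#>        WT drug    1 17.16001 7.003643 4
#>        WT drug   10 63.46698 9.425527 4
#>        WT drug   30 64.85907 4.760541 4

fit_hill(occ$per_animal$dose, occ$per_animal$ro_pct)
#> <Hill-Langmuir: ro_max 65.03%, d50 1.647 mg/kg, n 2.06>
```

Occupancy rises steeply between 1 and 10 mg/kg and saturates near 65%
— the sub-maximal plateau characteristic of a modulatory S1R ligand.
`run_pipeline()` chains all stages (simulation, input-function and 2TCM
fits, occupancy, %ID/g, autoradiography, statistics) and writes a
Table-1-style group summary plus a JSON statistics report;
`inst/scripts/occupet.R` wraps it for the shell.

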