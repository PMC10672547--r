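---
title: "Tumor 3D morphometry and cutoff-stratified survival: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tumor 3D morphometry and cutoff-stratified survival: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(morphosurv)
```

## The analysis in one paragraph

`morphosurv` implements a pretreatment prognosis analysis for solid tumors
(developed with oral squamous cell carcinoma in mind) built on two
three-dimensional descriptors of the segmented tumor mass: the volume
**Vt** (cm³) and the Wadell sphericity **St**. Both are computed from a
closed triangle mesh of the tumor surface. The markers are then treated
exactly as a clinical biostatistician would treat any continuous
prognostic candidate: group comparison by Student's t-test, optimal-cutoff
derivation from the ROC curve via the Youden index, cutoff-stratified
Kaplan–Meier curves compared by the log-rank test, and univariate plus
multivariate Cox proportional-hazards models for two outcomes —
disease recurrence and tumor-related death.

## Morphometrics

For a closed surface with enclosed volume $V_p$ and surface area $A_p$,
the Wadell sphericity is

$$S \;=\; \frac{\pi^{1/3}\,(6 V_p)^{2/3}}{A_p},$$

the surface area of the sphere of volume $V_p$ divided by $A_p$. A sphere
has $S = 1$; by the isoperimetric inequality every other closed surface
has $S < 1$, so lower values mean a more irregular, less compact surface.
$S$ is dimensionless and invariant under uniform scaling — a property the
test suite asserts to $10^{-12}$ relative tolerance.

Volume is the absolute value of the signed-tetrahedron sum over faces
(divergence theorem); area is the sum of half cross-product magnitudes.
Taking the absolute value makes the result robust to a globally flipped
orientation (a warning is still raised, because a negative signed volume
indicates an inward-facing export convention). Meshes are cleaned at read
time — duplicate vertices merged at $10^{-6}$ mm, zero-area faces
dropped — so that the watertightness invariant (every edge shared by
exactly two faces) is checkable downstream. Non-watertight meshes are
*rejected* for volume computation rather than repaired silently: a
clinical segmentation with holes should be fixed upstream, not patched
invisibly inside a statistics package.

All internal computation is in mm; `Vt` is reported in cm³ (mm³/1000) to
match how clinical tables report tumor volume.

### From voxel masks to meshes

Segmentations often arrive as binary voxel masks rather than meshes.
`mesh_from_mask()` extracts the 0.5 iso-surface of the zero-padded
occupancy field by marching tetrahedra on the Kuhn six-tetrahedron cell
decomposition, which triangulates space consistently and therefore yields
a watertight mesh by construction, with vertices scaled by the voxel
spacing (anisotropic spacings supported).

One numerical choice matters here. Iso-surfacing the *raw* 0/1 field
produces a faceted staircase whose area overestimates the true surface by
tens of percent even though the volume is nearly unbiased — the classic
digitized-boundary artefact. We therefore smooth the binary field with an
isotropic Gaussian of $\sigma = 1$ voxel before extraction. On a
digitized sphere of radius 20 voxels this brings both volume and area to
within about 1% of the analytic values, which is the accuracy the
package's own geometry tests demand. $\sigma$ is exposed
(`presmooth_sigma`), and `0` restores the raw-binary extraction. When the
foreground is so small that smoothing leaves nothing above the iso-level
(an isolated voxel, a 1-voxel-thick filament), the raw field is used
instead and a message is emitted; under that fallback a single unit
voxel yields a solid of exactly 0.5 mm³, a convention pinned by a
regression test. Very thin structures are the known weak spot of any
smoothed extraction and are documented as such, not hidden.

A voxel-counting volume (`mask_voxel_volume()`) is kept as an independent
cross-check; mesh and voxel volumes agree within 5% on blob-like masks of
radius ≥ 10 voxels, and the test suite asserts this.

## The synthetic-data module

No patient data ship with the package; instead every downstream stage is
exercised on synthetic data whose defaults describe a realistic surgical
oral-cancer cohort of **n = 95**:

* covariate marginals — advanced T stage 68%, nodal involvement 44%,
  perineural invasion 21%, lymphovascular infiltration 5%, extracapsular
  spread 26%, positive margins 12%, grading low/moderate/high
  16/71/13%;
* `Vt` log-normal with (untruncated) mean 13.6 cm³ and SD 18.2 cm³,
  truncated to 0.1–96.2 cm³. The SD exceeding the mean implies strong
  right skew, which the log-normal captures; truncation to the plausible
  clinical range trims roughly the top 0.7% of the law and lowers the
  realised mean by a few percent, which the distribution-match tests
  allow for;
* `St` Beta on (0, 1) matched to mean 0.63, SD 0.10 — a bounded quantity
  needs a bounded law;
* event times exponential with log-hazard linear in the covariates, `Vt`
  (per cm³) and `1 − St`, default hazard ratios of 2.5 (N+) and 2.3
  (PNI) for recurrence, 6.0 (N+), 4.8 (PNI) and 3.4 (margins) for death;
* censoring: random exponential censoring (rate 1/45 per month) plus
  administrative censoring at 122 months. Baseline hazards
  (0.0010 and 0.00017 per month) were calibrated once, by simulation at
  n = 20000, so that about 72% of patients remain recurrence-free, about
  84% avoid tumor-related death, and mean observed follow-up is near 31
  months under the default effects. These constants are study-design
  choices and are not revisited by the tests.

The mesh generator (`generate_tumor_mesh()`) radially perturbs a unit
icosphere with band-limited angular noise (cosine lobes of wavenumbers
1..`harmonic_order` around random directions), then rescales isotropically
to the requested volume, so sphericity is controlled by the amplitude
while volume is exact. It is deterministic per seed.

What the generator does **not** emulate: correlations among covariates
(marginals only — hooks exist via `covariate_frequencies` but realistic
joint structure is unknown), dependence between the recurrence and death
processes (they are drawn independently, with no semi-competing-risks
structure), non-proportional hazards, measurement error in segmentation,
and the relationship between tumor site and shape. Passing tests
therefore demonstrate the *statistical machinery* is correct and
calibrated, not that any particular clinical effect size is real.

```{r generator, eval = TRUE}
coh <- generate_cohort(cohort_params(n = 95, seed = 1))
coh
```

## Cutoffs

`roc_curve()` evaluates sensitivity/specificity at every midpoint between
consecutive distinct marker values (plus ±∞), so the trapezoid AUC equals
the Mann–Whitney statistic exactly — asserted to $10^{-12}$ against a
pairwise-counting oracle. `youden_cutoff()` maximises
$J = \text{sens} + \text{spec} − 1$, choosing the marker orientation so
$J \ge 0$. Ties in $J$ are broken deterministically: first toward the
more balanced sensitivity/specificity pair, then toward the smaller
threshold. A patient exactly on the cutoff belongs to the
below-or-equal group. Events are binarized as status at last follow-up,
mirroring common clinical practice; this ignores follow-up length, and a
time-dependent ROC is deliberately out of scope. Separate cutoffs are
derived per outcome (recurrence vs death), not one shared cutoff.

## Survival statistics

Kaplan–Meier estimation, the log-rank test and Cox regression are
delegated to the `survival` package behind the module interfaces, and
each delegated operation is validated against an independent brute-force
oracle in the tests: a hand product-limit computation, an explicit
risk-table log-rank with hypergeometric variance on all instances with
n ≤ 12, and a fine-grid maximisation of a hand-written Breslow partial
likelihood on a constructed six-subject instance (agreement to $10^{-4}$).

Choices the tables do not determine by themselves:

* **Tie handling** — Breslow by default (adequate at cohort scale),
  Efron behind a flag.
* **t-test** — pooled-variance Student by default, because that is what
  "Student's t-test" means literally; Welch behind a flag, since tumor
  volume variances are conspicuously unequal between groups.
* **Grading** — coded ordinally (low 0, moderate 1, high 2) so it enters
  the screen as a single trend coefficient.
* **Morphometrics in the multivariate model** — continuous by default
  (`Vt` per cm³, `St` per unit; note a per-cm³ hazard ratio is
  numerically close to 1 by construction), with a config switch to
  cutoff-dichotomized coding (`Vt_above_cutoff`, `St_below_cutoff`).
  Both codings are legitimate and reported results should state which
  was used.
* **Median and restricted-mean survival** are both always reported,
  since "average survival" is ambiguous in clinical prose.

The multivariate model keeps clinical parameters with univariate
p ≤ 0.05, then appends `Vt` and `St`. If nothing passes the screen the
model contains the morphometrics only (with a logged note); if events are
fewer than model terms an events-per-variable warning is raised.

## A calibration caveat the package asserts about itself

Stratifying survival at a cutoff *derived from the same data* inflates
the log-rank type-I error: the Youden search is an optimisation over
thresholds, and its optimism propagates into the p-value. The test suite
quantifies this on null cohorts (zero morphometric effects, 500
replicates at n = 95): a pre-specified median split rejects at close to
the nominal 5% (asserted within 2–9%), while Youden-cutoff
stratification rejects clearly more often than 5%. Users should treat
cutoff-stratified p-values as descriptive unless the cutoff was fixed in
advance.

## Validation problem sizes

The shipped tests run at sizes chosen to finish in minutes on one CPU
while still being informative: icosphere subdivision 5 (20,480 faces) for
the sphere-sphericity check; digitized spheres of radius 10–20 voxels for
mask geometry; 100–200 random instances for the ROC/Youden and
survival-oracle equivalences; 200 replicates at n = 500 for Cox coverage
(each 95% CI covers its generating coefficient in ≥ 90% of replicates);
500 replicates at n = 95 for null calibration; and five seeds of the full
n = 95 demo for the end-to-end property that the high-volume stratum
fares worse.

## Known limitations

* Segmentation itself is out of scope: masks and meshes are inputs, and
  their quality bounds everything downstream.
* Mask-derived area is accurate only for structures a few voxels thick;
  sub-voxel filaments fall back to the staircase surface.
* The two outcomes are modelled and simulated independently; there is no
  competing-risks machinery, and disease-specific survival is analysed
  with tumor-related death as the only event type.
* No proportional-hazards diagnostics beyond what `survival` itself
  offers on the returned `coxph` objects.
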