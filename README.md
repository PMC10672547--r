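# morphosurv

Pretreatment 3D morphometry and prognosis analysis for segmented solid
tumors, written for head-and-neck/oral-cancer research groups who have
tumor segmentations (STL meshes or binary voxel masks from CT) and
follow-up data, and want to evaluate two shape markers as prognostic
factors:

* **Tumor volume, Vt** (cm³) — enclosed volume of the segmented mass.
* **Tumor sphericity, St** — the Wadell sphericity

  S = π^(1/3) · (6 · V_p)^(2/3) / A_p,

  the surface area of the sphere with the particle's volume divided by
  the particle's own surface area. S = 1 for a perfect sphere and
  decreases toward 0 as the surface becomes more irregular — a candidate
  imaging surrogate for an infiltrative growth pattern.

The statistical pipeline is the standard clinical battery: Student's
t-tests between outcome groups, ROC/Youden-index cutoff derivation per
marker and outcome, cutoff-stratified Kaplan–Meier curves with log-rank
tests, and univariate plus multivariate Cox proportional-hazards models
for disease recurrence and tumor-related death. A synthetic-data module
generates tumor-like meshes with controllable sphericity and patient
cohorts with proportional-hazards outcomes, so the whole pipeline is
testable without patient data. See the methods vignette
(`vignettes/tumor-morphometry-survival.Rmd`) for the model, the numerical
choices, and the known limitations (including why data-driven cutoff
p-values are optimistic).

## Worked example

```r
library(morphosurv)

# a synthetic tumor: perturbed sphere rescaled to 13.6 cm^3
m <- generate_tumor_mesh(target_volume_cm3 = 13.6, amplitude = 0.3, seed = 7)
mesh_morphometrics(m)
#> tumor morphometrics: Vt = 13.600 cm^3, area = 28.835 cm^2, St = 0.9556

# full pipeline on a synthetic 95-patient cohort
rep <- run_pipeline(analysis_config(mode = "synthetic", n = 95, seed = 7))
rep$cutoffs
#>  marker    outcome cutoff     J   auc orientation sensitivity specificity
#>  Vt_cm3 recurrence 11.641 0.362 0.694        high       0.581       0.781
#>      St recurrence  0.611 0.202 0.480         low       0.452       0.750
#>  Vt_cm3      death  7.303 0.271 0.591        high       0.733       0.537
#>      St      death  0.692 0.229 0.446         low       0.867       0.363
```

The cutoff table reads: on this simulated cohort, a tumor volume above
11.6 cm³ best separates patients who recur from those who do not
(Youden J = 0.36), while for sphericity *low* values predict the event
(orientation `"low"`). Stratifying recurrence-free survival at the Vt
cutoff:

```r
subset(rep$stratified_survival, marker == "Vt_cm3" & outcome == "recurrence")
#>            group  n events median_months rmean_months logrank_p
#>  Vt_below_cutoff 63     13           114         89.3  0.000179
#>  Vt_above_cutoff 32     18            41         44.3  0.000179
```

Patients above the volume cutoff have far shorter recurrence-free
survival (restricted mean 44 vs 89 months; log-rank p < 0.001 — recall
the cutoff was optimised on the same data). The multivariate Cox model
appends the morphometrics to the clinical parameters that passed the
univariate screen:

```r
rep$multivariate$recurrence
#> cox_fit (recurrence, breslow ties): n = 95, events = 31
#>     term        p   hr      ci95
#>      pni   0.0318 2.45 1.08-5.55
#>  grading    0.402 0.70 0.31-1.60
#>       Vt 2.04e-05 1.04 1.02-1.06
#>       St    0.186 0.07 0.00-3.66
```

Here perineural invasion (HR 2.45 per positive status) and tumor volume
(HR 1.04 **per cm³**, i.e. ~3.4× across the interquartile volume range)
remain prognostic for recurrence. `write_report(rep, "out/")` serialises
every table (morphometrics, group summary, cutoffs, stratified survival,
KM step curves, univariate/multivariate tables, metadata) as delimited
text.

A command-line front end with verbs `demo`, `run`, `morphometrics`,
`cutoffs` and `survival` is installed under `inst/cli/morphosurv.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/morphosurv.R", package="morphosurv"))')" demo --n 95 --seed 1 --out runs/
```

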