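# paedz

Normative Z-scores and nomograms for the paediatric athlete
echocardiogram.

Pre-participation cardiac screening of young athletes must separate
training-induced remodelling (a larger ventricle, thicker walls, augmented
diastolic filling) from the cardiomyopathies that cause sudden cardiac
death — phenotypes that overlap. The separation is only as good as the
reference interval: a wall thickness is abnormal relative to athletes of
the same body size and age, and reference equations borrowed from other
populations leave Z-scores that still correlate with body surface area
(BSA) or age. `paedz` is a toolkit for building, auditing and applying
covariate-adjusted reference models for this setting, aimed at
echocardiography researchers and screening programmes.

## The models

Structural measures (LV dimensions, mass, volume, aortic root, left
atrium) follow an allometric mean in BSA with an additive age term, and a
*regressed SD* (RSD) linear in both covariates to capture the growth-driven
heteroscedasticity:

    z = (obs − (a·BSA^b + c·age)) / (d + e·BSA + f·age)

Functional Doppler/TDI measures follow a second-order polynomial in
chronological age:

    z = (obs − (a·age² + b·age + c)) / (d + e·age)

LVEF is covariate-independent and normal; its lower reference limit is
`mean − 2·SD` (the value at Z = −2). The RSD is estimated by ordinary
least squares of `sqrt(π/2)·|residual|` on the covariates (the half-normal
identity `E|X| = σ·sqrt(2/π)`), so Z-scores are calibrated to unit SD
without log-transforming the data.

The package covers: cohort CSV I/O with validation and BSA derivation
(Mosteller/DuBois/Haycock), model fitting (`fit_structural`,
`fit_functional`, `fit_lvef`, `fit_cohort`), Z computation/inversion and
nomogram tables/plots, a residual-independence diagnostics battery
(residual correlations, ethnicity t-test, Δ-R², exceedance rates) for
fitted or externally published equations, longitudinal athlete tracking,
a synthetic cohort generator emulating a 417-athlete Arab/black male
screening population, and a small CLI (`inst/cli/paedz.R`).

## Worked example

```r
library(paedz)

# A 13-year-old athlete, BSA 1.76 m², septal wall thickness 8.5 mm,
# scored under the published IVSd reference coefficients:
ivsd <- structural_model("IVSd", a = 6.055, b = -0.020, c = 0.031,
                         d = 1.100, e = 0.062, f = -0.008)
compute_z(8.5, ivsd, bsa = 1.76, age = 13)
#> # A tibble: 1 × 9
#>   measure observed predicted_mean   rsd     z centile out_of_range hr_caution
#>   <chr>      <dbl>          <dbl> <dbl> <dbl>   <dbl> <lgl>        <lgl>
#> 1 IVSd         8.5           6.39  1.11  1.91    97.2 FALSE        FALSE
#> # ℹ 1 more variable: out_of_envelope <lgl>
```

The wall is 1.91 covariate-adjusted SDs above the mean expected for this
body size and age — 97th centile, below the |z| ≥ 2 investigation
threshold. The full pipeline runs off a data frame:

```r
cohort <- simulate_cohort(sim_config(seed = 1))   # or load_cohort("cohort.csv")
fit <- fit_structural(cohort, "IVSd")
glance(fit)
#> # A tibble: 1 × 6
#>   measure     n status       mean_z  sd_z  rsd_r2
#>   <chr>   <int> <chr>         <dbl> <dbl>   <dbl>
#> 1 IVSd      417 converged 0.0000781  1.01 0.00532
```

A fitted-sample z mean near 0 and SD near 1 say the model is calibrated on
its own cohort; `evaluate_model(cohort, fit)` then checks that z is
independent of BSA, age, biological age, heart rate and ethnicity, and
`plot_nomogram(fit$model, cohort)` draws the Z = 0, ±1, ±2 reference
chart. Published equations from other populations can be audited on your
cohort via `external_model_spec()` + `evaluate_external_model()`.

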