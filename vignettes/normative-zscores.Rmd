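---
title: "Normative Z-score models for the paediatric athlete echocardiogram"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Normative Z-score models for the paediatric athlete echocardiogram}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(paedz)
```

## The problem

Regular, sustained training remodels the paediatric heart: the left
ventricle dilates, walls thicken, diastolic filling is augmented. The same
phenotypes — in exaggerated form — mark the cardiomyopathies that dominate
sudden cardiac death in young athletes. Screening therefore needs
*population-specific* reference intervals: a measurement is only abnormal
relative to what athletes of the same body size and age would show.
Reference equations derived from non-athletes, or from athletes of a
different ethnic background, leave residual structure — Z-scores that still
correlate with body surface area (BSA) or age — and misclassify at both
tails.

`paedz` implements the full normative-modelling pipeline for this setting:
model fitting with explicitly heteroscedastic scatter, Z-score computation
and inversion, nomogram construction, a residual-independence diagnostics
battery that audits any candidate reference equation, and a synthetic
cohort generator so every stage is testable without access to screening
data.

## The two model families

**Structural measures** (LV internal diameter, wall thicknesses, LV mass
and volume, aortic root, left atrium) scale allometrically with body size
and carry a residual age effect:

$$z = \frac{\mathrm{obs} - \left(a \cdot \mathrm{BSA}^{b} + c \cdot \mathrm{age}\right)}{d + e \cdot \mathrm{BSA} + f \cdot \mathrm{age}}$$

**Functional measures** (transmitral Doppler velocities, deceleration
time, tissue-Doppler annular velocities, E/e′ ratios) are modelled on
chronological age alone, with a second-order polynomial mean:

$$z = \frac{\mathrm{obs} - \left(a \cdot \mathrm{age}^{2} + b \cdot \mathrm{age} + c\right)}{d + e \cdot \mathrm{age}}$$

**LVEF** shows no association with BSA or age in this population and is
normally distributed, so its reference model is simply a mean and SD; the
lower reference limit is `mean − 2·SD`, the value at Z = −2 (`n_sd = 1.96`
is available for a strict 95% limit).

### The mean-form ambiguity

The allometric mean is sometimes typeset ambiguously as
`a*BSA(b+c*age)`, which admits two readings:

* **additive age** — $a \cdot \mathrm{BSA}^{b} + c \cdot \mathrm{age}$;
* **age in the exponent** — $a \cdot \mathrm{BSA}^{(b + c \cdot \mathrm{age})}$.

Only the additive form reproduces the published worked example (IVSd
8.5 mm, BSA 1.76 m², age 13 → z = 1.91; the exponent form gives 0.89), so
`additive_age` is the default and `exponent_age` is retained as an explicit
option for models published in that form.

```{r}
ivsd <- structural_model("IVSd", a = 6.055, b = -0.020, c = 0.031,
                         d = 1.100, e = 0.062, f = -0.008)
compute_z(8.5, ivsd, bsa = 1.76, age = 13)
```

### Sign convention

Z-scores are always reported signed. The functional worked example
(average E/e′ of 4.3 at age 15) lies *below* its predicted mean of 6.24,
so the equation yields z = −1.87; displays that quote a magnitude should
use `abs(z)` explicitly.

## Regressed SD: heteroscedasticity without transformation

Residual scatter grows with body size for most structural measures, and
log-transformation (the classical remedy) distorts the back-transformed
intervals. Instead the SD itself is modelled as a linear function of the
covariates — a *regressed SD* (RSD). Estimation uses the half-normal
identity: if residuals are centred normal with SD $\sigma(x)$, then
$E|r| = \sigma(x)\sqrt{2/\pi}$, so ordinary least squares of
$\sqrt{\pi/2}\,|r|$ on the covariates estimates $\sigma(x)$ directly.

Note the direction of the constant: the absolute residuals must be
*multiplied by* $\sqrt{\pi/2} \approx 1.253$ (equivalently divided by
$\sqrt{2/\pi} \approx 0.798$). Descriptions of this procedure sometimes
print the reciprocal constant; only $\sqrt{\pi/2}$ yields fitted-sample
Z-scores with SD near 1, which the test suite verifies by simulation. The
constant is an argument (`k`) on every fitting function for completeness.

The fitted SD surface is floored at a small positive value (`1e-6` by
default) when evaluated, and every model constructor verifies the RSD is
strictly positive across the validity envelope (BSA 0.8–2.4 m², age
11–18 y) — a model that extrapolates to non-positive SD inside the
envelope is rejected at construction.

## Fitting

`fit_structural()` runs three stages:

1. **Mean** — nonlinear least squares (Levenberg–Marquardt via
   `minpack.lm`, at most 200 iterations, tolerance 1e-10), initialised
   deterministically from the log–log regression of the measure on BSA
   (slope → `b`, `exp(intercept)` → `a`, `c = 0`). Deterministic
   initialisation makes fits byte-reproducible without random restarts.
2. **RSD** — `estimate_rsd()` on the stage-1 residuals against BSA and age.
3. **Optional reweighting** (`reweight = TRUE`, default off) — exactly one
   mean refit with weights $1/\hat\sigma^2$. The default is off because the
   reference procedure is single-pass; one cycle is provided for users who
   want variance-weighted means, and the fits agree closely on
   well-behaved cohorts.

`fit_functional()` is ordinary least squares on `{age², age, 1}` followed
by the RSD regression on age. `fit_lvef()` takes the mean and SD, screens
normality (Shapiro–Wilk, warning at p < 0.05 — a warning rather than an
abort because the limit may still be serviceable) and reports a Pearson
association screen against BSA and both ages at α = 0.01 so a
covariate-dependent ejection fraction is flagged rather than silently
averaged.

The per-measure sample floor is 30 complete records (configurable). This
is deliberately below a design target of ≥120 per age group for nomogram
construction: the floor guards against degenerate fits, not against
under-powered reference intervals, and production use should bring
substantially more data.

## The diagnostics battery

A reference equation is adequate when the Z-scores it assigns leave no
residual structure. `evaluate_model()` (and `evaluate_external_model()`
for published equations supplied as an `external_model_spec`) runs:

* **Residual correlations** — Pearson r of z against BSA, chronological
  age, biological (skeletal) age and heart rate, flagged at p ≤ 0.05
  (effect) and p ≤ 0.01 (interaction). P-values are raw: the reference
  analysis reports them without multiple-testing correction, and so does
  the battery — users comparing many measures should keep that in mind.
* **Ethnicity effect** — pooled-variance two-sample t-test on z; the mean
  difference is defined as black − Arab (stated because the direction is
  otherwise ambiguous).
* **Δ-R²** — `delta_r2_ethnicity()` refits the mean per ethnicity stratum
  and reports the additional variance explained. Both R² values share the
  total sum of squares about the grand mean as denominator
  (stratified R² = 1 − pooled-across-strata RSS / total SS), so the delta
  is well defined; a gain of ≥5 percentage points is flagged as clinically
  significant, below that ethnic-specific coefficients are deemed
  unnecessary. Only means are refit per stratum — the comparison concerns
  explained variance, so no RSD estimation is involved.
* **Exceedance rates** — per-ethnicity percentages with z ≥ 2 and z ≤ −2;
  the boundary counts as exceeding.
* **Heart-rate caution** — peak A velocity, E/A and septal a′ retain a
  physiologic HR dependency that the models deliberately do not normalise
  away (HR–flow–tissue coupling is too entangled to adjust for cleanly);
  their results carry an `hr_caution` flag and the battery adds a note
  when a z–HR correlation is detected.

## The synthetic cohort generator

No public screening dataset exists for this population, so
`simulate_cohort()` generates one with the statistical structure the
analysis assumes — it is the package's test bench, not a data product. The
defaults emulate the reference population:

* 297 Arab and 120 black male athletes; chronological age uniform on
  11–18 y.
* BSA = 0.25 + 0.093·age + N(0, 0.13), truncated to 0.8–2.4 m² by
  one-at-a-time rejection (documented so the random stream, and hence the
  cohort, is reproducible for a given seed). This gives mean BSA ≈ 1.6 m²,
  SD ≈ 0.23, and an age–BSA correlation of ≈ 0.8 — the strong collinearity
  real growth data show.
* Biological age = chronological age + 1.0 + 0.5·(black) + N(0, 0.6),
  reproducing the observed half-year skeletal-maturity lead of black
  athletes at equal chronological age.
* Heart rate = 95 − 1.5·age + N(0, 10) bpm.
* Each measurement is its model mean plus normal noise with SD equal to
  the model's regressed SD (so true-model Z-scores are standard normal by
  construction); LVEF ~ N(60, 5.8) independent of all covariates, making
  the lower reference limit 48.4%.

IVSd and average E/e′ use published worked-example coefficients as ground
truth; the remaining measures use physiologically plausible synthetic
coefficients (chosen once for this age range and labelled as synthetic in
`default_true_models()`), because no further coefficient tables are
available in the source text. The generator does **not** emulate
inter-observer measurement error, training-dose or sport-specific
remodelling, non-uniform age recruitment, or any true ethnicity effect on
cardiac measures — so passing diagnostics on synthetic data show the
pipeline is *correct and calibrated*, not that real athlete data are this
clean.

`noise_scale = 0` gives the noiseless limit (measurements equal their
model means exactly), which the suite uses for exact-recovery tests.

## What the validation shows — and its limits

The test suite verifies, among other things: both published worked
examples to 2 dp; the half-normal calibration of `estimate_rsd()` (σ
recovered within 1% at n = 10⁵); exact coefficient recovery on noiseless
cohorts; fitted-sample Z means within ±0.15 and SDs within 0.85–1.15
across replicate cohorts at n = 417; type-I rates of the correlation flags
consistent with their nominal 5% level (uniform null p-values); >90%
power at α = 0.01 against a planted r = 0.2 covariate dependence at
n = 417; and the `compute_z`/`invert_z` identity to 1e-12.

Two quantities are *not* recoverable at the study's own scale, and the
suite documents rather than hides this: the allometric exponent `b` of a
measure like IVSd (true value −0.020) and the age coefficient `c` (0.031)
have sampling errors at n = 417 comparable to or larger than the
coefficients themselves, because the residual SD (≈1.1 mm) is large
relative to the covariate leverage and BSA and age are strongly collinear.
The mean *surface* is recovered accurately — the individual near-zero
coefficients are not separately identifiable. Users fitting their own
cohorts should judge fits by the residual diagnostics and the fitted-z
calibration, not by comparing individual small coefficients across
studies.

Problem sizes in the suite were chosen to keep the default run fast:
recovery uses 20 replicate cohorts of n = 417, calibration nulls use 200
replicates, and large-sample checks use 10⁴–10⁵ draws.

## Numerical and design choices

* Units: linear dimensions in mm, LV mass in g, volumes in mL, velocities
  in cm/s, DecT in ms, LVEF in %, ratios dimensionless. The loader
  converts declared cm columns to mm.
* BSA: Mosteller by default; DuBois and Haycock selectable. Coefficient
  files record the formula used, so fitted models are self-describing.
* Z is displayed to 2 dp in the CLI (matching clinical reporting); full
  precision is kept internally and in all files.
* Out-of-envelope covariates flag the result (`out_of_envelope`) rather
  than erroring — screening encounters boundary cases — but a non-positive
  extrapolated RSD is a hard error naming the inputs.
* Missing biological age or heart rate: the affected diagnostics are
  skipped with a note, never imputed.
* The longitudinal drift flag in `track_athlete()` (|Δz| ≥ 1.5 between
  visits) is a screening convenience with no clinical derivation;
  threshold configurable.

## Known limitations

* Models are male-athlete-specific by construction of the emulated
  population; application to female or untrained paediatric populations is
  out of scope.
* The generator's non-IVSd/E-e′ truths are synthetic; absolute values of
  recovered coefficients for those measures validate the machinery, not
  any published nomogram.
* No bootstrap or profile confidence intervals on fitted coefficients, and
  no LMS/GAMLSS-style centile modelling — the linear-RSD normal model is
  the scope.
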