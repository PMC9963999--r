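Package: paedz
Title: Normative Z-Scores and Nomograms for Paediatric Athlete Echocardiography
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Fits and applies normative reference models for echocardiographic
    measurements in paediatric athletes. Structural measures (left-ventricular
    dimensions, mass and volume, aortic root, left atrium) follow an allometric
    mean in body surface area with an additive chronological-age term;
    functional Doppler and tissue-Doppler measures follow a second-order
    polynomial in age. Heteroscedasticity is handled by a regressed standard
    deviation (RSD), estimated by linear regression of half-normal-scaled
    absolute residuals on the covariates. The package computes and inverts
    covariate-dependent Z-scores, builds nomogram tables and plots (Z = 0,
    +/-1, +/-2 lines), runs a residual-independence diagnostics battery
    (residual correlations, ethnicity effects, delta-R-squared, exceedance
    rates) on fitted or externally published models, and ships a synthetic
    cohort generator emulating a screening population of Arab and black male
    athletes aged 11-18 for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
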