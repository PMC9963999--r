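#' True generating models for the synthetic cohort
#'
#' The per-measure coefficients the synthetic generator treats as ground
#' truth. IVSd and average E/e' use the published worked-example
#' coefficients; every other measure uses physiologically plausible synthetic
#' values (chosen once for boys aged 11-18 with BSA 0.8-2.4 m^2, documented
#' in the methods vignette) because no further coefficient tables are
#' reproduced in the available text.
#'
#' @return A named list of `paedz` model objects.
#' @export
default_true_models <- function() {
  m <- list(
    # Structural: a (scale), b (BSA exponent), c (units/year); SD d + e*BSA + f*age
    structural_model("LVIDd", a = 34,    b = 0.50,   c = 0.45,
                     d = 2.0,  e = 0.80,  f = 0.02,  unit = "mm"),
    structural_model("IVSd",  a = 6.055, b = -0.020, c = 0.031,
                     d = 1.100, e = 0.062, f = -0.008, unit = "mm"),
    structural_model("PWTd",  a = 5.5,   b = 0.10,   c = 0.12,
                     d = 0.8,  e = 0.20,  f = 0.0,   unit = "mm"),
    structural_model("LVM",   a = 60,    b = 1.20,   c = 3.0,
                     d = 8.0,  e = 6.0,   f = 0.20,  unit = "g"),
    structural_model("LV_vol", a = 55,   b = 1.10,   c = 1.5,
                     d = 8.0,  e = 5.0,   f = 0.20,  unit = "mL"),
    structural_model("AoR",   a = 22,    b = 0.40,   c = 0.25,
                     d = 1.5,  e = 0.50,  f = 0.0,   unit = "mm"),
    structural_model("LAD",   a = 24,    b = 0.45,   c = 0.30,
                     d = 1.8,  e = 0.60,  f = 0.01,  unit = "mm"),
    structural_model("LA_vol", a = 20,   b = 1.00,   c = 0.60,
                     d = 4.0,  e = 3.0,   f = 0.10,  unit = "mL"),
    # Functional: mean a*age^2 + b*age + c; SD d + e*age
    functional_model("E",        a = 0.10,  b = -3.8,   c = 125,
                     d = 16.0, e = -0.20, unit = "cm/s"),
    functional_model("A",        a = 0.05,  b = -2.0,   c = 70,
                     d = 10.0, e = -0.10, unit = "cm/s"),
    functional_model("E_A",      a = 0.004, b = -0.16,  c = 3.6,
                     d = 0.60, e = -0.01, unit = ""),
    functional_model("DecT",     a = 0.20,  b = -2.0,   c = 160,
                     d = 30.0, e = -0.50, unit = "ms"),
    functional_model("septal_e", a = -0.01, b = 0.20,   c = 11,
                     d = 2.2,  e = -0.03, unit = "cm/s"),
    functional_model("septal_a", a = 0.005, b = -0.15,  c = 8,
                     d = 1.2,  e = -0.01, unit = "cm/s"),
    functional_model("lateral_e", a = -0.01, b = 0.25,  c = 16,
                     d = 3.0,  e = -0.05, unit = "cm/s"),
    functional_model("avg_E_e", a = 0.009, b = -0.418, c = 10.485,
                     d = 1.413, e = -0.025, unit = ""),
    lvef_model(mean = 60, sd = 5.8)
  )
  names(m) <- purrr::map_chr(m, "measure")
  m
}

#' Simulation configuration
#'
#' Defines the synthetic screening population: 297 Arab and 120 black male
#' athletes aged 11-18 by default. BSA grows linearly with age plus normal
#' noise, truncated to 0.8-2.4 m^2 (defaults give mean 1.6, SD 0.23 and
#' corr(age, BSA) of about 0.8). Biological age leads chronological age by
#' 1.0 y on average, with an extra +0.5 y in black athletes. Heart rate
#' declines with age. Measurements are drawn from the `true_models` means
#' with noise SD equal to the model's regressed SD (floored at
#' `noise_floor`); LVEF is drawn independently of all covariates.
#'
#' @param n_arab,n_black Group sizes.
#' @param age_range Uniform chronological-age range (years).
#' @param bsa_growth List `intercept` (m^2), `slope` (m^2/year), `sd` (m^2).
#' @param bio_age List `baseline` (years), `black_extra` (years), `sd` (years).
#' @param hr List `intercept` (bpm), `slope` (bpm/year), `sd` (bpm).
#' @param true_models Named list of generating models
#'   (default [default_true_models()]).
#' @param noise_scale Multiplier on every measurement-noise SD; `0` gives the
#'   noiseless limit in which each measurement equals its model mean exactly.
#' @param noise_floor Minimum noise SD (measure units).
#' @param seed Integer seed; identical configs generate identical cohorts.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_arab = 297, n_black = 120, age_range = c(11, 18),
                       bsa_growth = list(intercept = 0.25, slope = 0.093, sd = 0.13),
                       bio_age = list(baseline = 1.0, black_extra = 0.5, sd = 0.6),
                       hr = list(intercept = 95, slope = -1.5, sd = 10),
                       true_models = default_true_models(),
                       noise_scale = 1, noise_floor = 1e-6, seed = 1) {
  stopifnot(n_arab + n_black >= 2, diff(age_range) > 0,
            bsa_growth$sd >= 0, bio_age$sd >= 0, hr$sd >= 0,
            noise_scale >= 0, noise_floor > 0)
  structure(list(n_arab = n_arab, n_black = n_black, age_range = age_range,
                 bsa_growth = bsa_growth, bio_age = bio_age, hr = hr,
                 true_models = true_models, noise_scale = noise_scale,
                 noise_floor = noise_floor, seed = seed),
            class = "sim_config")
}

# One-at-a-time rejection sampling from a truncated normal, so the random
# stream (and hence the cohort) is reproducible for a given config.
rtruncnorm_reject <- function(n, mean, sd, lower, upper) {
  if (sd == 0) return(pmin(pmax(mean, lower), upper))
  out <- numeric(n)
  for (i in seq_len(n)) {
    repeat {
      x <- rnorm(1, mean[i], sd)
      if (x >= lower && x <= upper) break
    }
    out[i] <- x
  }
  out
}

#' Generate a synthetic athlete cohort
#'
#' Draws a cohort with the covariate and measurement structure the normative
#' analysis assumes, so fitting and diagnostics can be exercised end to end.
#' Z-scores computed on the output with the generating models are standard
#' normal by construction.
#'
#' @param config A [sim_config()].
#' @return A cohort tibble (same shape as [load_cohort()] output).
#' @export
simulate_cohort <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_arab + config$n_black
  ethnicity <- c(rep("arab", config$n_arab), rep("black", config$n_black))
  age <- runif(n, config$age_range[1], config$age_range[2])
  g <- config$bsa_growth
  bsa <- rtruncnorm_reject(n, g$intercept + g$slope * age, g$sd, 0.8, 2.4)
  b <- config$bio_age
  bio_age <- age + b$baseline + b$black_extra * (ethnicity == "black") +
    rnorm(n, 0, b$sd)
  h <- config$hr
  heart_rate <- h$intercept + h$slope * age + rnorm(n, 0, h$sd)

  cohort <- tibble::tibble(
    athlete_id = sprintf("ath%04d", seq_len(n)),
    ethnicity = ethnicity,
    chronological_age = age,
    biological_age = bio_age,
    height = NA_real_, weight = NA_real_,
    bsa = bsa,
    heart_rate = heart_rate
  )

  for (m in config$true_models) {
    mu <- model_mean(m, bsa = bsa, age = age)
    sigma <- model_rsd(m, bsa = bsa, age = age)
    if (any(sigma <= 0)) {
      warn(sprintf(
        "Generating SD for '%s' non-positive over BSA [%.2f, %.2f], age [%.1f, %.1f]; floored.",
        m$measure, min(bsa), max(bsa), min(age), max(age)))
    }
    sigma <- pmax(sigma, config$noise_floor) * config$noise_scale
    cohort[[m$measure]] <- mu + rnorm(n, 0, 1) * sigma
  }
  cohort
}
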