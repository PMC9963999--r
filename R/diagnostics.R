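#' Residual correlations of Z-scores with covariates
#'
#' An adequate Z-score model leaves z independent of the covariates it
#' adjusted for (and of those it deliberately did not). Computes Pearson r
#' of z against each covariate with a two-sided t-test p-value (n - 2 df).
#' Following the study's thresholds, p <= 0.05 flags a significant effect
#' and p <= 0.01 a significant interaction. No multiple-testing correction
#' is applied across the battery; p-values are reported raw.
#'
#' @param cohort A cohort tibble.
#' @param z Z-score vector aligned to the cohort rows.
#' @param covariates Covariate columns to test.
#' @return A tibble: `covariate`, `r`, `p_value`, `n`, `significant`
#'   (p <= 0.05), `interaction` (p <= 0.01), `note`.
#' @export
residual_correlations <- function(cohort, z,
                                  covariates = c("bsa", "chronological_age",
                                                 "biological_age", "heart_rate")) {
  stopifnot(length(z) == nrow(cohort))
  purrr::map_dfr(covariates, function(v) {
    x <- cohort[[v]]
    ok <- !is.na(x) & !is.na(z)
    if (sum(ok) < 3) {
      return(tibble::tibble(covariate = v, r = NA_real_, p_value = NA_real_,
                            n = sum(ok), significant = FALSE,
                            interaction = FALSE,
                            note = "fewer than 3 complete pairs; skipped"))
    }
    if (sd(x[ok]) == 0 || sd(z[ok]) == 0) {
      return(tibble::tibble(covariate = v, r = NA_real_, p_value = NA_real_,
                            n = sum(ok), significant = FALSE,
                            interaction = FALSE,
                            note = "zero variance; correlation undefined"))
    }
    ct <- cor.test(x[ok], z[ok])
    tibble::tibble(covariate = v, r = unname(ct$estimate), p_value = ct$p.value,
                   n = sum(ok), significant = ct$p.value <= 0.05,
                   interaction = ct$p.value <= 0.01, note = NA_character_)
  })
}

#' Ethnicity effect on Z-scores
#'
#' Pooled-variance two-sample t-test of z between the two ethnicity groups.
#' The mean difference is reported as black minus Arab (stated explicitly
#' because the direction convention is otherwise ambiguous).
#'
#' @param cohort A cohort tibble with an `ethnicity` column of exactly two
#'   levels, each with at least two observations.
#' @param z Z-score vector aligned to the cohort rows.
#' @return A one-row tibble: `mean_z_arab`, `mean_z_black`,
#'   `mean_difference`, `t_statistic`, `p_value`, `n_arab`, `n_black`,
#'   `significant`.
#' @export
ethnicity_effect <- function(cohort, z) {
  stopifnot(length(z) == nrow(cohort))
  ok <- !is.na(z) & !is.na(cohort$ethnicity)
  eth <- cohort$ethnicity[ok]
  z <- z[ok]
  lev <- sort(unique(eth))
  if (length(lev) != 2) abort("Exactly two ethnicity levels are required.")
  g1 <- z[eth == lev[1]]   # arab sorts first for the study labels
  g2 <- z[eth == lev[2]]
  if (length(g1) < 2 || length(g2) < 2) {
    abort("Each ethnicity group needs at least two Z-scores.")
  }
  if (sd(z) == 0) {
    tt <- list(statistic = c(t = 0), p.value = 1)
  } else {
    tt <- t.test(g2, g1, var.equal = TRUE)
  }
  tibble::tibble(
    mean_z_arab = mean(g1), mean_z_black = mean(g2),
    mean_difference = mean(g2) - mean(g1),
    t_statistic = unname(tt$statistic), p_value = tt$p.value,
    n_arab = length(g1), n_black = length(g2),
    significant = tt$p.value <= 0.05
  )
}

#' Additional variance explained by ethnicity-specific models
#'
#' Refits the measure's normative mean separately per ethnicity stratum and
#' compares explained variance against the pooled fit. Both R-squared values
#' share the same denominator (total sum of squares about the grand mean):
#' stratified R2 = 1 - (summed within-stratum residual SS) / total SS, so
#' the delta is well defined. A delta of at least 0.05 (5 percentage points
#' of variance) is flagged as clinically significant; below that,
#' ethnicity-specific coefficients are considered unnecessary.
#'
#' @param cohort A cohort tibble with two ethnicity levels.
#' @param measure Measure column to refit.
#' @param family `"structural"` or `"functional"`.
#' @param mean_form Mean form for structural fits.
#' @param floor_n Per-stratum sample floor.
#' @return A one-row tibble: `pooled_r2`, `stratified_r2`, `delta`,
#'   `clinically_significant`.
#' @export
delta_r2_ethnicity <- function(cohort, measure,
                               family = c("structural", "functional"),
                               mean_form = "additive_age", floor_n = 30) {
  family <- match.arg(family)
  covars <- if (family == "structural") c("bsa", "chronological_age") else "chronological_age"
  dat <- complete_measure(cohort, measure, covars)
  lev <- sort(unique(dat$ethnicity))
  if (length(lev) != 2) abort("Exactly two ethnicity levels are required.")

  # Only the mean fit matters here: the delta compares explained variance of
  # the mean surfaces, so no RSD estimation (or envelope validation) is run.
  stratum_rss <- function(d, label) {
    if (nrow(d) < floor_n) {
      abort(sprintf("Stratum '%s' has %d records for '%s'; the fitting floor is %d.",
                    label, nrow(d), measure, floor_n))
    }
    if (family == "structural") {
      df <- data.frame(y = d[[measure]], bsa = d$bsa,
                       age = d$chronological_age)
      fit <- structural_mean_nls(df, mean_form)
      if (inherits(fit, "error")) {
        abort(sprintf("Fit failed in stratum '%s' for measure '%s': %s",
                      label, measure, conditionMessage(fit)))
      }
      sum(resid(fit)^2)
    } else {
      fit <- lm(d[[measure]] ~ I(d$chronological_age^2) + d$chronological_age)
      sum(resid(fit)^2)
    }
  }

  tss <- sum((dat[[measure]] - mean(dat[[measure]]))^2)
  rss_pooled <- stratum_rss(dat, "pooled")
  rss_strat <- sum(purrr::map_dbl(lev, function(l) {
    stratum_rss(dat[dat$ethnicity == l, , drop = FALSE], l)
  }))
  pooled_r2 <- 1 - rss_pooled / tss
  strat_r2 <- 1 - rss_strat / tss
  delta <- strat_r2 - pooled_r2
  tibble::tibble(pooled_r2 = pooled_r2, stratified_r2 = strat_r2,
                 delta = delta, clinically_significant = delta >= 0.05)
}

#' Per-ethnicity exceedance rates
#'
#' Percentage of each ethnicity group with z >= 2 and with z <= -2 (the
#' boundary counts as exceeding). Denominators are the non-missing z in each
#' group; empty groups are absent from the output.
#'
#' @param cohort A cohort tibble.
#' @param z Z-score vector aligned to the cohort rows.
#' @return A tibble: `ethnicity`, `n`, `pct_above` (z >= 2), `pct_below`
#'   (z <= -2).
#' @export
exceedance_rates <- function(cohort, z) {
  stopifnot(length(z) == nrow(cohort))
  tibble::tibble(ethnicity = cohort$ethnicity, z = z) |>
    dplyr::filter(!is.na(.data$z), !is.na(.data$ethnicity)) |>
    dplyr::group_by(.data$ethnicity) |>
    dplyr::summarise(
      n = dplyr::n(),
      pct_above = 100 * mean(.data$z >= 2),
      pct_below = 100 * mean(.data$z <= -2),
      .groups = "drop"
    )
}

#' Specification of an externally published Z-score model
#'
#' Wraps coefficients of a published model so it can be evaluated on a
#' cohort without re-deriving it. Supported forms:
#' * `structural_additive`: z = (obs - (a*BSA^b + c*age)) / (d + e*BSA + f*age)
#' * `structural_exponent`: z = (obs - a*BSA^(b + c*age)) / (d + e*BSA + f*age)
#' * `polynomial_age`: z = (obs - (a*age^2 + b*age + c)) / (d + e*age)
#' * `log_linear_bsa`: z = (ln(obs) - (alpha + beta*ln(BSA))) / sigma
#'   (the log-transformed BSA models common in earlier reference equations)
#'
#' @param measure Measure the model applies to.
#' @param form One of the forms above.
#' @param coefficients Named list of coefficients for the declared form.
#' @param source_label Free-text provenance label.
#' @return A list of class `external_model_spec`.
#' @export
external_model_spec <- function(measure,
                                form = c("structural_additive",
                                         "structural_exponent",
                                         "polynomial_age", "log_linear_bsa"),
                                coefficients, source_label = "") {
  form <- match.arg(form)
  need <- switch(form,
    structural_additive = c("a", "b", "c", "d", "e", "f"),
    structural_exponent = c("a", "b", "c", "d", "e", "f"),
    polynomial_age      = c("a", "b", "c", "d", "e"),
    log_linear_bsa      = c("alpha", "beta", "sigma")
  )
  missing_co <- setdiff(need, names(coefficients))
  if (length(missing_co)) {
    abort(sprintf("Form '%s' requires coefficient(s): %s.", form,
                  paste(missing_co, collapse = ", ")))
  }
  structure(list(measure = measure, form = form,
                 coefficients = coefficients[need],
                 source_label = source_label),
            class = "external_model_spec")
}

#' Z-scores under an external model specification
#'
#' @param cohort A cohort tibble containing the spec's measure and required
#'   covariates.
#' @param spec An [external_model_spec()].
#' @return Numeric z vector aligned to cohort rows (NA where inputs missing).
#' @export
compute_external_z <- function(cohort, spec) {
  stopifnot(inherits(spec, "external_model_spec"))
  if (!spec$measure %in% names(cohort)) {
    abort(sprintf("Measure '%s' is not a column of the cohort.", spec$measure))
  }
  co <- spec$coefficients
  obs <- cohort[[spec$measure]]
  age <- cohort$chronological_age
  bsa <- cohort$bsa
  switch(spec$form,
    structural_additive = (obs - (co$a * bsa^co$b + co$c * age)) /
      (co$d + co$e * bsa + co$f * age),
    structural_exponent = (obs - co$a * bsa^(co$b + co$c * age)) /
      (co$d + co$e * bsa + co$f * age),
    polynomial_age = (obs - (co$a * age^2 + co$b * age + co$c)) /
      (co$d + co$e * age),
    log_linear_bsa = (log(obs) - (co$alpha + co$beta * log(bsa))) / co$sigma
  )
}

#' Model-adequacy battery for a fitted or external model
#'
#' Runs the full residual-independence battery on the Z-scores a model
#' assigns to a cohort: residual correlations with BSA, chronological age,
#' biological age and heart rate; the ethnicity effect; per-ethnicity
#' exceedance rates; and a heart-rate caution note where relevant. This is
#' the workflow used both to audit externally published models and to
#' confirm a freshly fitted model leaves no residual structure.
#'
#' @param cohort A cohort tibble.
#' @param model A `paedz` model object, a `paedz_fit`, or an
#'   [external_model_spec()].
#' @return An object of class `diagnostics_report`: `measure`, `source`,
#'   `mean_z`, `sd_z`, `correlations`, `ethnicity_test`, `exceedance`,
#'   `hr_dependency_note`.
#' @export
evaluate_model <- function(cohort, model) {
  if (inherits(model, "paedz_fit")) model <- model$model
  if (inherits(model, "external_model_spec")) {
    z <- compute_external_z(cohort, model)
    measure <- model$measure
    src <- if (nzchar(model$source_label)) model$source_label else "external"
  } else if (inherits(model, "paedz_model")) {
    measure <- model$measure
    if (!measure %in% names(cohort)) {
      abort(sprintf("Measure '%s' is not a column of the cohort.", measure))
    }
    z <- rep(NA_real_, nrow(cohort))
    ok <- !is.na(cohort[[measure]])
    if (model$family == "structural") ok <- ok & !is.na(cohort$bsa)
    if (model$family %in% c("structural", "functional")) {
      ok <- ok & !is.na(cohort$chronological_age)
    }
    z[ok] <- compute_z(cohort[[measure]][ok], model,
                       bsa = cohort$bsa[ok],
                       age = cohort$chronological_age[ok])$z
    src <- "fitted"
  } else {
    abort("`model` must be a paedz model, paedz_fit or external_model_spec.")
  }
  corr <- residual_correlations(cohort, z)
  eth <- tryCatch(ethnicity_effect(cohort, z), error = function(e) NULL)
  hr_row <- corr[corr$covariate == "heart_rate", ]
  hr_note <- if (nrow(hr_row) == 1 && isTRUE(hr_row$significant)) {
    sprintf("Z retains a heart-rate dependency (r = %.3f, p = %.3g); interpret with caution at unusual resting HR.",
            hr_row$r, hr_row$p_value)
  } else {
    NA_character_
  }
  structure(list(measure = measure, source = src,
                 mean_z = mean(z, na.rm = TRUE), sd_z = sd(z, na.rm = TRUE),
                 correlations = corr, ethnicity_test = eth,
                 exceedance = exceedance_rates(cohort, z),
                 hr_dependency_note = hr_note, z = z),
            class = "diagnostics_report")
}

#' @rdname evaluate_model
#' @param spec An [external_model_spec()].
#' @export
evaluate_external_model <- function(cohort, spec) {
  stopifnot(inherits(spec, "external_model_spec"))
  evaluate_model(cohort, spec)
}

#' @export
print.diagnostics_report <- function(x, ...) {
  cat(sprintf("<diagnostics_report> %s (%s): mean z %.3f, sd z %.3f\n",
              x$measure, x$source, x$mean_z, x$sd_z))
  cat("Residual correlations:\n")
  print(as.data.frame(x$correlations), row.names = FALSE, digits = 3)
  if (!is.null(x$ethnicity_test)) {
    cat(sprintf("Ethnicity (black - arab): diff %.3f, t = %.2f, p = %.3g\n",
                x$ethnicity_test$mean_difference, x$ethnicity_test$t_statistic,
                x$ethnicity_test$p_value))
  }
  cat("Exceedance (%):\n")
  print(as.data.frame(x$exceedance), row.names = FALSE, digits = 3)
  if (!is.na(x$hr_dependency_note)) cat("Note:", x$hr_dependency_note, "\n")
  invisible(x)
}
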