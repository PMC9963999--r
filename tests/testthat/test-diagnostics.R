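null_cohort_z <- function(seed, n_arab = 297, n_black = 120) {
  co <- simulate_cohort(sim_config(n_arab = n_arab, n_black = n_black,
                                   seed = seed))
  tm <- default_true_models()
  z <- compute_z(co$IVSd, tm$IVSd, bsa = co$bsa, age = co$chronological_age)$z
  list(cohort = co, z = z)
}

test_that("residual correlations are null for true-model z and detect planted effects", {
  big <- simulate_cohort(sim_config(n_arab = 7000, n_black = 3000, seed = 5))
  tm <- default_true_models()
  z <- compute_z(big$IVSd, tm$IVSd, bsa = big$bsa,
                 age = big$chronological_age)$z
  tab <- residual_correlations(big, z)
  expect_true(all(abs(tab$r) < 0.03))
  expect_false(any(tab$significant))
  # planted BSA dependence flagged as an interaction (p <= 0.01)
  set.seed(41)
  zp <- 0.5 * scale(big$bsa)[, 1] + rnorm(nrow(big))
  tabp <- residual_correlations(big, zp)
  expect_true(tabp$interaction[tabp$covariate == "bsa"])
  # degenerate covariates are skipped or marked undefined
  co <- tiny_cohort()
  co$heart_rate <- c(70, NA, NA)
  tab2 <- residual_correlations(co, c(0.1, -0.2, 0.3))
  expect_match(tab2$note[tab2$covariate == "heart_rate"], "skipped")
  co$biological_age <- 15
  tab3 <- residual_correlations(co, c(0.1, -0.2, 0.3))
  expect_match(tab3$note[tab3$covariate == "biological_age"], "zero variance")
})

test_that("ethnicity effect is null under exchangeability and finds planted shifts", {
  nc <- null_cohort_z(seed = 51)
  res <- ethnicity_effect(nc$cohort, nc$z)
  expect_lt(abs(res$t_statistic), 3)
  expect_equal(res$n_arab, 297)
  expect_equal(res$n_black, 120)
  # planted +0.315 shift in the black group: median recovered difference
  diffs <- vapply(1:40, function(s) {
    nc <- null_cohort_z(seed = 500 + s)
    z <- nc$z + 0.315 * (nc$cohort$ethnicity == "black")
    ethnicity_effect(nc$cohort, z)$mean_difference
  }, numeric(1))
  se_med <- 1.2533 * sqrt(1 / 297 + 1 / 120) / sqrt(40)
  expect_equal(median(diffs), 0.315, tolerance = 3 * se_med / 0.315)
  # degenerate equal groups: t = 0, p = 1
  co <- tibble::tibble(ethnicity = c("arab", "arab", "black", "black"))
  res0 <- ethnicity_effect(co, c(1, 1, 1, 1))
  expect_equal(res0$t_statistic, 0)
  expect_equal(res0$p_value, 1)
  expect_error(ethnicity_effect(co[1:2, ], c(1, 1)), "two ethnicity levels")
})

test_that("delta-R2 is small under a shared model and large for ethnic-specific means", {
  cohorts <- lapply(61:65, function(s) simulate_cohort(sim_config(seed = s)))
  d0 <- dplyr::bind_rows(lapply(cohorts, delta_r2_ethnicity,
                                measure = "IVSd", family = "structural"))
  expect_lt(median(d0$delta), 0.01)
  expect_true(all(d0$delta >= 0))  # stratified fits can only reduce residual SS
  expect_false(any(d0$clinically_significant))
  d0f <- dplyr::bind_rows(lapply(cohorts, delta_r2_ethnicity,
                                 measure = "avg_E_e", family = "functional"))
  expect_lt(median(d0f$delta), 0.01)
  expect_false(any(d0f$clinically_significant))
  # intercept shift of one residual SD in the black stratum
  co <- cohorts[[1]]
  co2 <- co
  sd_ivsd <- 1.105
  co2$IVSd <- co2$IVSd + sd_ivsd * (co2$ethnicity == "black")
  d1 <- delta_r2_ethnicity(co2, "IVSd", "structural")
  expect_gt(d1$delta, 0.05)
  expect_true(d1$clinically_significant)
  # duplicated groups are exactly symmetric: delta ~ 0 up to solver tolerance
  half <- co[co$ethnicity == "arab", ]
  half2 <- dplyr::mutate(half, ethnicity = "black",
                         athlete_id = paste0(athlete_id, "b"))
  dup <- dplyr::bind_rows(half, half2)
  dd <- delta_r2_ethnicity(dup, "IVSd", "structural")
  expect_lt(abs(dd$delta), 1e-8)
  # a stratum below the floor is refused with its name
  small <- co[c(which(co$ethnicity == "arab"),
                which(co$ethnicity == "black")[1:10]), ]
  expect_error(delta_r2_ethnicity(small, "IVSd", "structural"), "black")
})

test_that("exceedance rates obey the boundary convention and invariances", {
  co <- tibble::tibble(ethnicity = rep("arab", 3))
  res <- exceedance_rates(co, c(2.0, -2.0, 0))
  expect_equal(res$pct_above, 100 / 3, tolerance = 1e-12)
  expect_equal(res$pct_below, 100 / 3, tolerance = 1e-12)
  res0 <- exceedance_rates(co, c(0, 0, 0))
  expect_equal(res0$pct_above, 0)
  expect_equal(res0$pct_below, 0)
  # invariant to record order
  nc <- null_cohort_z(seed = 71)
  perm <- sample(nrow(nc$cohort))
  expect_equal(dplyr::arrange(exceedance_rates(nc$cohort[perm, ], nc$z[perm]),
                              ethnicity),
               dplyr::arrange(exceedance_rates(nc$cohort, nc$z), ethnicity))
  # empty groups are simply absent
  co2 <- tibble::tibble(ethnicity = c("arab", NA))
  expect_equal(nrow(exceedance_rates(co2, c(1, 2))), 1)
})

test_that("external model evaluation reproduces the audit workflow", {
  co <- simulate_cohort(sim_config(seed = 81))
  tm <- default_true_models()
  # spec equal to the generating model: no flags
  spec_true <- external_model_spec(
    "IVSd", "structural_additive",
    coefficients = list(a = 6.055, b = -0.020, c = 0.031,
                        d = 1.100, e = 0.062, f = -0.008),
    source_label = "generating truth")
  rep_true <- evaluate_external_model(co, spec_true)
  expect_lt(abs(rep_true$mean_z), 0.15)
  expect_false(any(rep_true$correlations$significant &
                     rep_true$correlations$covariate %in%
                       c("bsa", "chronological_age")))
  # z agrees with compute_z on the same model
  expect_equal(rep_true$z,
               compute_z(co$IVSd, tm$IVSd, bsa = co$bsa,
                         age = co$chronological_age)$z, tolerance = 1e-12)

  # misspecified log-linear BSA model leaves residual age structure
  big <- simulate_cohort(sim_config(n_arab = 1400, n_black = 600, seed = 82))
  ll <- lm(log(LVIDd) ~ log(bsa), data = big)
  spec_log <- external_model_spec(
    "LVIDd", "log_linear_bsa",
    coefficients = list(alpha = coef(ll)[[1]], beta = coef(ll)[[2]],
                        sigma = sd(resid(ll))),
    source_label = "log-linear audit")
  rep_log <- evaluate_external_model(big, spec_log)
  expect_true(rep_log$correlations$significant[
    rep_log$correlations$covariate == "chronological_age"])

  # doubling sigma halves both tails relative to the correct spec
  spec_wide <- external_model_spec(
    "IVSd", "structural_additive",
    coefficients = list(a = 6.055, b = -0.020, c = 0.031,
                        d = 2 * 1.100, e = 2 * 0.062, f = 2 * -0.008))
  z_true <- compute_external_z(co, spec_true)
  z_wide <- compute_external_z(co, spec_wide)
  expect_equal(z_wide, z_true / 2, tolerance = 1e-12)
  expect_lte(sum(abs(z_wide) >= 2), sum(abs(z_true) >= 2))

  expect_error(external_model_spec("IVSd", "structural_additive",
                                   coefficients = list(a = 1, b = 2)),
               "requires coefficient")
})

test_that("a fitted model passes its own diagnostics battery", {
  co <- simulate_cohort(sim_config(seed = 91))
  fit <- fit_structural(co, "IVSd")
  rep <- evaluate_model(co, fit)
  expect_lt(abs(rep$mean_z), 0.15)
  expect_false(rep$ethnicity_test$significant)
  expect_s3_class(rep, "diagnostics_report")
  expect_output(print(rep), "Residual correlations")
})
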