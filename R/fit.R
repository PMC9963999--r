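#' Regressed-SD estimation from residuals
#'
#' Estimates a standard deviation that varies linearly with covariates
#' (heteroscedasticity) by ordinary least squares of scaled absolute
#' residuals on an intercept plus the covariates. The scaling constant `k`
#' converts the mean absolute deviation of a centred normal to its SD via
#' the half-normal identity `E|X| = sigma * sqrt(2/pi)`, so the default is
#' `k = sqrt(pi/2)` (about 1.253). When evaluated, the fitted SD surface is
#' floored at a configurable positive minimum.
#'
#' @param residuals Numeric residual vector (measure units).
#' @param covariates Numeric matrix or data frame of covariates (one row per
#'   residual), or `NULL` for an intercept-only (homoscedastic) fit.
#' @param k Half-normal scaling constant applied to `|residuals|`.
#' @param floor Minimum admissible SD when the fitted surface is evaluated.
#'
#' @return An object of class `rsd_fit` with elements `coefficients`
#'   (intercept first), `scaling_constant`, `n`, `r2` and `degenerate`.
#' @export
estimate_rsd <- function(residuals, covariates = NULL, k = sqrt(pi / 2),
                         floor = 1e-6) {
  stopifnot(k > 0, floor > 0)
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    stopifnot(nrow(covariates) == length(residuals))
    if (length(residuals) < ncol(covariates) + 2) {
      abort("Need at least p + 2 residuals to regress an SD on p covariates.")
    }
    if (qr(cbind(1, covariates))$rank < ncol(covariates) + 1) {
      abort("Singular design in regressed-SD estimation.")
    }
  }
  y <- k * abs(residuals)
  degenerate <- all(residuals == 0)
  if (degenerate) {
    warn("All residuals are zero; regressed SD set to the floor.")
    p <- if (is.null(covariates)) 0 else ncol(covariates)
    cf <- c(floor, rep(0, p))
    names(cf) <- c("(Intercept)", colnames(covariates))
    fit <- NULL
    r2 <- NA_real_
  } else if (is.null(covariates)) {
    cf <- c(`(Intercept)` = mean(y))
    r2 <- 0
  } else {
    fit <- lm(y ~ covariates)
    cf <- coef(fit)
    names(cf) <- c("(Intercept)", colnames(covariates))
    r2 <- summary(fit)$r.squared
  }
  structure(list(coefficients = cf, scaling_constant = k,
                 n = length(residuals), r2 = r2, floor = floor,
                 degenerate = degenerate),
            class = "rsd_fit")
}

# Evaluate an rsd_fit surface at covariate values, applying the floor.
predict_rsd <- function(rsd_fit, covariates = NULL) {
  cf <- rsd_fit$coefficients
  out <- if (is.null(covariates)) cf[1] else {
    as.vector(cbind(1, as.matrix(covariates)) %*% cf)
  }
  pmax(out, rsd_fit$floor)
}

# Nonlinear least squares for the allometric mean, deterministically
# initialised from the log-log regression of y on BSA. Returns the nls fit,
# or the error condition on non-convergence.
structural_mean_nls <- function(df, mean_form, weights = NULL) {
  ll <- lm(log(y) ~ log(bsa), data = df)
  start <- list(a = exp(coef(ll)[[1]]), b = coef(ll)[[2]], c = 0)
  form <- if (mean_form == "additive_age") {
    y ~ a * bsa^b + c * age
  } else {
    y ~ a * bsa^(b + c * age)
  }
  ctrl <- minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-10, ptol = 1e-10)
  tryCatch(
    if (is.null(weights)) {
      minpack.lm::nlsLM(form, data = df, start = start, control = ctrl)
    } else {
      df$.w <- weights
      minpack.lm::nlsLM(form, data = df, start = start, weights = .w,
                        control = ctrl)
    },
    error = function(e) e
  )
}

complete_measure <- function(cohort, measure, covars) {
  if (!measure %in% names(cohort)) {
    abort(sprintf("Measure '%s' is not a column of the cohort.", measure))
  }
  keep <- !is.na(cohort[[measure]])
  for (v in covars) keep <- keep & !is.na(cohort[[v]])
  cohort[keep, , drop = FALSE]
}

new_paedz_fit <- function(model, rsd_fit, convergence, z, n) {
  structure(list(model = model, rsd_fit = rsd_fit, convergence = convergence,
                 residual_summary = list(mean_z = mean(z), sd_z = sd(z)),
                 n = n),
            class = "paedz_fit")
}

#' Fit an allometric structural model to a cohort
#'
#' Three-stage procedure. Stage 1 fits the mean by nonlinear least squares
#' (Levenberg-Marquardt, [minpack.lm::nlsLM()]), deterministically
#' initialised from an ordinary log-log regression of the measure on BSA
#' (slope -> `b`, `exp(intercept)` -> `a`, `c = 0`) so fits are reproducible
#' without random restarts. Stage 2 estimates the regressed SD from the mean
#' residuals against BSA and age via [estimate_rsd()]. Stage 3 (off by
#' default) performs one reweighted mean refit with weights `1/rsd^2`.
#'
#' @param cohort A cohort tibble.
#' @param measure Name of the structural measure column.
#' @param mean_form `"additive_age"` (default) or `"exponent_age"`.
#' @param reweight Run the single reweighting cycle of stage 3.
#' @param floor_n Minimum number of complete records (default 30).
#' @param k Half-normal scaling constant passed to [estimate_rsd()].
#' @param bsa_formula Recorded on the emitted model.
#'
#' @return An object of class `paedz_fit`: `model` (a [structural_model()]),
#'   `rsd_fit`, `convergence` (status and iterations) and
#'   `residual_summary` (mean and SD of the fitted-sample Z-scores).
#' @export
fit_structural <- function(cohort, measure,
                           mean_form = c("additive_age", "exponent_age"),
                           reweight = FALSE, floor_n = 30, k = sqrt(pi / 2),
                           bsa_formula = "mosteller") {
  mean_form <- match.arg(mean_form)
  dat <- complete_measure(cohort, measure, c("bsa", "chronological_age"))
  if (nrow(dat) < floor_n) {
    abort(sprintf("Only %d complete records for '%s'; the sample floor is %d.",
                  nrow(dat), measure, floor_n))
  }
  df <- data.frame(y = dat[[measure]], bsa = dat$bsa,
                   age = dat$chronological_age)
  nlfit <- structural_mean_nls(df, mean_form)
  if (inherits(nlfit, "error")) {
    return(structure(list(model = NULL, rsd_fit = NULL,
                          convergence = list(status = "failed",
                                             message = conditionMessage(nlfit),
                                             iterations = NA_integer_),
                          residual_summary = NULL, n = nrow(df)),
                     class = "paedz_fit"))
  }
  covars <- cbind(bsa = df$bsa, age = df$age)
  rsd <- estimate_rsd(resid(nlfit), covars, k = k)
  if (reweight) {
    w <- 1 / predict_rsd(rsd, covars)^2
    refit <- structural_mean_nls(df, mean_form, weights = w)
    if (!inherits(refit, "error")) {
      nlfit <- refit
      rsd <- estimate_rsd(df$y - predict(nlfit), covars, k = k)
    }
  }
  cf <- coef(nlfit)
  rcf <- rsd$coefficients
  model <- structural_model(measure, a = cf[["a"]], b = cf[["b"]], c = cf[["c"]],
                            d = rcf[[1]], e = rcf[[2]], f = rcf[[3]],
                            mean_form = mean_form,
                            unit = catalog_unit(measure), bsa_formula = bsa_formula)
  z <- (df$y - structural_mean(model, df$bsa, df$age)) /
    pmax(structural_rsd(model, df$bsa, df$age), rsd$floor)
  conv <- nlfit$convInfo
  new_paedz_fit(model, rsd,
                list(status = "converged",
                     iterations = conv$finIter %||% NA_integer_),
                z, nrow(df))
}

#' Fit a polynomial functional model to a cohort
#'
#' Ordinary least squares of the measure on chronological age and age
#' squared, followed by [estimate_rsd()] of the residuals on age. A constant
#' measure column degenerates gracefully to `a = b = 0`, `c = constant` with
#' a degenerate-RSD warning.
#'
#' @inheritParams fit_structural
#' @param measure Name of the functional (Doppler/TDI) measure column.
#' @return A `paedz_fit` whose `model` is a [functional_model()].
#' @export
fit_functional <- function(cohort, measure, floor_n = 30, k = sqrt(pi / 2)) {
  dat <- complete_measure(cohort, measure, "chronological_age")
  if (nrow(dat) < floor_n) {
    abort(sprintf("Only %d complete records for '%s'; the sample floor is %d.",
                  nrow(dat), measure, floor_n))
  }
  df <- data.frame(y = dat[[measure]], age = dat$chronological_age)
  if (sd(df$y) == 0) {
    cf <- c(0, 0, df$y[1])
    res <- rep(0, nrow(df))
  } else {
    olsfit <- lm(y ~ I(age^2) + age, data = df)
    cf <- c(coef(olsfit)[["I(age^2)"]], coef(olsfit)[["age"]],
            coef(olsfit)[["(Intercept)"]])
    res <- resid(olsfit)
  }
  rsd <- estimate_rsd(res, cbind(age = df$age), k = k)
  rcf <- rsd$coefficients
  model <- functional_model(measure, a = cf[1], b = cf[2], c = cf[3],
                            d = rcf[[1]], e = rcf[[2]],
                            unit = catalog_unit(measure))
  z <- (df$y - functional_mean(model, df$age)) /
    pmax(functional_rsd(model, df$age), rsd$floor)
  new_paedz_fit(model, rsd, list(status = "converged", iterations = 1L),
                z, nrow(df))
}

#' Fit an LVEF reference model
#'
#' LVEF is modelled as homoscedastic normal: the model is the cohort mean
#' and SD, and the lower reference limit is `mean - 2*SD` (the value at
#' Z = -2). Normality is assessed by Shapiro-Wilk at alpha = 0.05 (warning
#' on rejection, never an abort), and an association screen against BSA,
#' chronological and biological age (Pearson, alpha = 0.01) is reported so a
#' covariate-dependent LVEF is flagged rather than silently averaged.
#'
#' @inheritParams fit_structural
#' @param measure LVEF column name (default `"LVEF"`).
#' @param n_sd Multiplier defining the lower reference limit.
#' @return A `paedz_fit` whose `model` is an [lvef_model()], with an extra
#'   `associations` tibble (covariate, r, p_value, flagged).
#' @export
fit_lvef <- function(cohort, measure = "LVEF", floor_n = 30, n_sd = 2) {
  dat <- complete_measure(cohort, measure, character())
  if (nrow(dat) < floor_n) {
    abort(sprintf("Only %d LVEF values; the sample floor is %d.",
                  nrow(dat), floor_n))
  }
  y <- dat[[measure]]
  if (sd(y) == 0) {
    warn("LVEF has zero variance; lower reference limit equals the mean.")
    model <- structure(
      list(measure = "LVEF", unit = "%", family = "lvef",
           mean = y[1], sd = 0, n_sd = n_sd, lower_reference_limit = y[1]),
      class = c("lvef_model", "paedz_model"))
    norm_p <- NA_real_
  } else {
    sw <- shapiro.test(if (length(y) > 5000) sample(y, 5000) else y)
    norm_p <- sw$p.value
    if (norm_p < 0.05) {
      warn(sprintf("LVEF normality rejected by Shapiro-Wilk (p = %.3g); the normal reference limit may be inaccurate.", norm_p))
    }
    model <- lvef_model(mean(y), sd(y), n_sd = n_sd)
  }
  assoc <- purrr::map_dfr(
    c("bsa", "chronological_age", "biological_age"),
    function(v) {
      x <- dat[[v]]
      ok <- !is.na(x)
      if (sum(ok) < 3 || sd(y) == 0 || sd(x[ok]) == 0) {
        return(tibble::tibble(covariate = v, r = NA_real_, p_value = NA_real_,
                              n = sum(ok), flagged = FALSE))
      }
      ct <- cor.test(x[ok], y[ok])
      tibble::tibble(covariate = v, r = unname(ct$estimate),
                     p_value = ct$p.value, n = sum(ok),
                     flagged = ct$p.value <= 0.01)
    })
  z <- if (model$sd > 0) (y - model$mean) / model$sd else rep(0, length(y))
  out <- new_paedz_fit(model, NULL,
                       list(status = "converged", iterations = 1L),
                       z, length(y))
  out$normality_p <- norm_p
  out$associations <- assoc
  out
}

catalog_unit <- function(measure) {
  cat0 <- default_measure_catalog()
  i <- match(measure, cat0$measure)
  if (is.na(i)) "" else cat0$unit[i]
}

#' Fit every catalogued measure in a cohort
#'
#' Applies [fit_structural()], [fit_functional()] or [fit_lvef()] per the
#' measure catalog and returns the successful fits.
#'
#' @inheritParams fit_structural
#' @param measures Measures to fit (default: all catalogued in the cohort).
#' @return A named list of `paedz_fit` objects.
#' @export
fit_cohort <- function(cohort, measures = NULL,
                       mean_form = c("additive_age", "exponent_age"),
                       reweight = FALSE, floor_n = 30, k = sqrt(pi / 2)) {
  mean_form <- match.arg(mean_form)
  cat0 <- measure_catalog(cohort)
  cat0 <- cat0[!is.na(cat0$family), ]
  if (!is.null(measures)) cat0 <- cat0[cat0$measure %in% measures, ]
  fits <- purrr::pmap(cat0[, c("measure", "family")], function(measure, family) {
    switch(family,
      structural = fit_structural(cohort, measure, mean_form = mean_form,
                                  reweight = reweight, floor_n = floor_n, k = k),
      functional = fit_functional(cohort, measure, floor_n = floor_n, k = k),
      lvef       = fit_lvef(cohort, measure, floor_n = floor_n)
    )
  })
  names(fits) <- cat0$measure
  fits
}

#' @export
print.paedz_fit <- function(x, ...) {
  if (is.null(x$model)) {
    cat("<paedz_fit> FAILED:", x$convergence$message, "\n")
    return(invisible(x))
  }
  print(x$model)
  cat(sprintf("  n = %d, %s; fitted-z mean %.3f, sd %.3f\n", x$n,
              x$convergence$status,
              x$residual_summary$mean_z, x$residual_summary$sd_z))
  invisible(x)
}

#' Tidy a fitted normative model
#'
#' One row per coefficient with columns `term`, `estimate` and `component`
#' (`"mean"` or `"rsd"`).
#'
#' @param x A `paedz_fit`.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy paedz_fit
#' @export
tidy.paedz_fit <- function(x, ...) {
  if (is.null(x$model)) return(tibble::tibble())
  co <- model_coefs(x$model)
  n_mean <- switch(x$model$family, structural = 3, functional = 3, lvef = 1)
  tibble::tibble(term = names(co), estimate = unname(co),
                 component = rep(c("mean", "rsd"),
                                 c(n_mean, length(co) - n_mean)))
}

#' One-row summary of a fitted normative model
#'
#' Reports sample size, convergence status, fitted-sample Z mean and SD, and
#' the RSD regression R-squared.
#'
#' @param x A `paedz_fit`.
#' @param ... Unused.
#' @return A one-row tibble.
#' @method glance paedz_fit
#' @export
glance.paedz_fit <- function(x, ...) {
  tibble::tibble(
    measure = if (is.null(x$model)) NA_character_ else x$model$measure,
    n = x$n,
    status = x$convergence$status,
    mean_z = x$residual_summary$mean_z %||% NA_real_,
    sd_z = x$residual_summary$sd_z %||% NA_real_,
    rsd_r2 = if (is.null(x$rsd_fit)) NA_real_ else x$rsd_fit$r2
  )
}
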