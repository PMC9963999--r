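#' Normative model for a structural (size) measure
#'
#' An allometric Z-score model relating a cardiac dimension to body surface
#' area and chronological age, with a regressed SD linear in both covariates:
#' \deqn{z = \frac{obs - (a \cdot BSA^b + c \cdot age)}{d + e \cdot BSA + f \cdot age}}
#' The alternative parse of the mean, \eqn{a \cdot BSA^{(b + c \cdot age)}}
#' (`mean_form = "exponent_age"`), is retained as a selectable form; only the
#' additive form reproduces the published worked example (see the methods
#' vignette).
#'
#' @param measure Measure name (e.g. `"IVSd"`).
#' @param a,b,c Mean coefficients: scale, BSA exponent, age term.
#' @param d,e,f Regressed-SD coefficients: intercept, per-BSA slope,
#'   per-year slope (measure units).
#' @param mean_form `"additive_age"` (default) or `"exponent_age"`.
#' @param unit Measurement unit (mm, g, mL).
#' @param bsa_formula BSA formula the covariate is expected to come from.
#'
#' @return An object of class `structural_model`.
#'
#' @details At construction the regressed SD `d + e*BSA + f*age` is checked to
#' be strictly positive across the validity envelope (BSA 0.8--2.4 m^2, age
#' 11--18 y); a model violating this is rejected.
#'
#' @examples
#' m <- structural_model("IVSd", a = 6.055, b = -0.020, c = 0.031,
#'                       d = 1.100, e = 0.062, f = -0.008)
#' compute_z(8.5, m, bsa = 1.76, age = 13)
#' @export
structural_model <- function(measure, a, b, c, d, e, f,
                             mean_form = c("additive_age", "exponent_age"),
                             unit = "mm",
                             bsa_formula = c("mosteller", "dubois", "haycock")) {
  mean_form <- match.arg(mean_form)
  bsa_formula <- match.arg(bsa_formula)
  stopifnot(is.numeric(a), is.numeric(b), is.numeric(c),
            is.numeric(d), is.numeric(e), is.numeric(f))
  if (a <= 0) abort("Scale coefficient `a` must be positive.")
  m <- structure(
    list(measure = as.character(measure), unit = unit, family = "structural",
         a = a, b = b, c = c, d = d, e = e, f = f,
         mean_form = mean_form, bsa_formula = bsa_formula),
    class = c("structural_model", "paedz_model")
  )
  check_rsd_envelope(m)
  m
}

#' Normative model for a functional (Doppler/TDI) measure
#'
#' A second-order polynomial Z-score model in chronological age with a
#' regressed SD linear in age:
#' \deqn{z = \frac{obs - (a \cdot age^2 + b \cdot age + c)}{d + e \cdot age}}
#'
#' @param measure Measure name (e.g. `"avg_E_e"`).
#' @param a,b,c Quadratic, linear and intercept mean coefficients.
#' @param d,e Regressed-SD intercept and per-year slope.
#' @param unit Measurement unit (cm/s, ms, or `""` for ratios).
#'
#' @return An object of class `functional_model`.
#' @examples
#' m <- functional_model("avg_E_e", a = 0.009, b = -0.418, c = 10.485,
#'                       d = 1.413, e = -0.025, unit = "")
#' compute_z(4.3, m, age = 15)
#' @export
functional_model <- function(measure, a, b, c, d, e, unit = "cm/s") {
  stopifnot(is.numeric(a), is.numeric(b), is.numeric(c),
            is.numeric(d), is.numeric(e))
  m <- structure(
    list(measure = as.character(measure), unit = unit, family = "functional",
         a = a, b = b, c = c, d = d, e = e),
    class = c("functional_model", "paedz_model")
  )
  check_rsd_envelope(m)
  m
}

#' Normative model for LV ejection fraction
#'
#' LVEF shows no association with BSA or age in the reference population, so
#' its Z-score uses a constant mean and SD. The lower reference limit is
#' `mean - n_sd * sd`, corresponding to Z = -2 with the default `n_sd = 2`
#' (1.96 available for a strict 95% limit).
#'
#' @param mean,sd Cohort mean and SD of LVEF (%).
#' @param n_sd Multiplier defining the lower reference limit (default 2).
#'
#' @return An object of class `lvef_model`.
#' @examples
#' lvef_model(60, 5.8)  # lower reference limit 48.4%
#' @export
lvef_model <- function(mean, sd, n_sd = 2) {
  stopifnot(is.numeric(mean), is.numeric(sd), sd >= 0)
  lrl <- mean - n_sd * sd
  if (!(lrl > 0 && lrl < mean && mean <= 100)) {
    abort("LVEF model requires 0 < lower reference limit < mean <= 100.")
  }
  structure(
    list(measure = "LVEF", unit = "%", family = "lvef",
         mean = mean, sd = sd, n_sd = n_sd, lower_reference_limit = lrl),
    class = c("lvef_model", "paedz_model")
  )
}

# Construction-time sweep: RSD must be strictly positive everywhere on the
# declared envelope. Linear in covariates, so checking the corners suffices.
check_rsd_envelope <- function(model) {
  if (inherits(model, "structural_model")) {
    corners <- expand.grid(bsa = ENVELOPE$bsa, age = ENVELOPE$age)
    vals <- model$d + model$e * corners$bsa + model$f * corners$age
  } else {
    vals <- model$d + model$e * ENVELOPE$age
  }
  if (any(vals <= 0)) {
    abort(sprintf(
      "Regressed SD for '%s' is non-positive within the validity envelope (min %.4g).",
      model$measure, min(vals)))
  }
  invisible(model)
}

#' @export
print.paedz_model <- function(x, ...) {
  co <- model_coefs(x)
  cat(sprintf("<%s> %s [%s]\n", class(x)[1], x$measure, x$unit))
  cat(" ", paste(sprintf("%s = %g", names(co), co), collapse = ", "), "\n")
  if (!is.null(x$mean_form)) cat("  mean form:", x$mean_form, "\n")
  invisible(x)
}

model_coefs <- function(model) {
  switch(model$family,
    structural = unlist(model[c("a", "b", "c", "d", "e", "f")]),
    functional = unlist(model[c("a", "b", "c", "d", "e")]),
    lvef       = unlist(model[c("mean", "sd")])
  )
}

#' Predicted mean of a structural measure
#'
#' Evaluates the allometric mean at given BSA and age. With the default
#' `additive_age` form this is \eqn{a \cdot BSA^b + c \cdot age}; with
#' `exponent_age` it is \eqn{a \cdot BSA^{(b + c \cdot age)}}.
#'
#' @param model A [structural_model()].
#' @param bsa BSA in m^2 (vectorised).
#' @param age Chronological age in years (vectorised).
#' @return Predicted mean in measure units.
#' @export
structural_mean <- function(model, bsa, age) {
  stopifnot(inherits(model, "structural_model"))
  if (any(bsa <= 0)) abort("`bsa` must be strictly positive.")
  if (model$mean_form == "additive_age") {
    model$a * bsa^model$b + model$c * age
  } else {
    model$a * bsa^(model$b + model$c * age)
  }
}

#' Regressed SD of a structural measure
#'
#' `d + e*BSA + f*age`; positivity over the envelope is guaranteed by the
#' model constructor, but out-of-envelope covariates yielding a non-positive
#' SD raise an error naming the inputs.
#'
#' @inheritParams structural_mean
#' @return SD in measure units.
#' @export
structural_rsd <- function(model, bsa, age) {
  stopifnot(inherits(model, "structural_model"))
  out <- model$d + model$e * bsa + model$f * age
  if (any(out <= 0)) {
    bad <- which(out <= 0)[1]
    abort(sprintf(
      "Regressed SD non-positive at BSA = %.3g, age = %.3g (outside the validity envelope of '%s').",
      bsa[bad], age[bad], model$measure))
  }
  out
}

#' Predicted mean of a functional measure
#'
#' `a*age^2 + b*age + c`.
#'
#' @param model A [functional_model()].
#' @param age Chronological age in years (vectorised).
#' @return Predicted mean in measure units.
#' @export
functional_mean <- function(model, age) {
  stopifnot(inherits(model, "functional_model"))
  model$a * age^2 + model$b * age + model$c
}

#' Regressed SD of a functional measure
#'
#' `d + e*age`.
#'
#' @inheritParams functional_mean
#' @return SD in measure units.
#' @export
functional_rsd <- function(model, age) {
  stopifnot(inherits(model, "functional_model"))
  out <- model$d + model$e * age
  if (any(out <= 0)) {
    bad <- which(out <= 0)[1]
    abort(sprintf(
      "Regressed SD non-positive at age = %.3g (outside the validity envelope of '%s').",
      age[bad], model$measure))
  }
  out
}

model_mean <- function(model, bsa = NULL, age = NULL) {
  switch(model$family,
    structural = structural_mean(model, bsa, age),
    functional = functional_mean(model, age),
    lvef       = model$mean
  )
}

model_rsd <- function(model, bsa = NULL, age = NULL) {
  switch(model$family,
    structural = structural_rsd(model, bsa, age),
    functional = functional_rsd(model, age),
    lvef       = model$sd
  )
}

require_covariates <- function(model, bsa, age) {
  if (model$family == "structural") {
    if (is.null(bsa) || anyNA(bsa)) abort("Structural model requires covariate `bsa`.")
    if (is.null(age) || anyNA(age)) abort("Structural model requires covariate `age`.")
  } else if (model$family == "functional") {
    if (is.null(age) || anyNA(age)) abort("Functional model requires covariate `age`.")
  }
  invisible(TRUE)
}

in_envelope <- function(model, bsa, age, n) {
  ok <- rep(TRUE, n)
  if (model$family == "structural") {
    ok <- ok & bsa >= ENVELOPE$bsa[1] & bsa <= ENVELOPE$bsa[2]
  }
  if (model$family %in% c("structural", "functional")) {
    ok <- ok & age >= ENVELOPE$age[1] & age <= ENVELOPE$age[2]
  }
  ok
}

#' Covariate-adjusted Z-score
#'
#' Computes the signed Z-score of one or more observations under a structural,
#' functional or LVEF model: `z = (observed - predicted mean) / regressed SD`.
#' The centile is the standard-normal CDF of z. `|z| >= 2` raises the
#' out-of-range flag; measures with a known residual heart-rate dependency
#' (peak A, E/A, septal a') carry a caution flag. Covariates outside the
#' validity envelope set `out_of_envelope` (a warning flag, not an error,
#' since screening practice meets boundary cases).
#'
#' @param observed Observed value(s) in the measure's native unit.
#' @param model A `paedz` model object.
#' @param bsa BSA in m^2 (required for structural models).
#' @param age Chronological age in years (required for structural and
#'   functional models).
#'
#' @return A tibble with one row per observation: `measure`, `observed`,
#'   `predicted_mean`, `rsd`, `z`, `centile` (%), `out_of_range`,
#'   `hr_caution`, `out_of_envelope`.
#'
#' @examples
#' ivsd <- structural_model("IVSd", 6.055, -0.020, 0.031, 1.100, 0.062, -0.008)
#' compute_z(8.5, ivsd, bsa = 1.76, age = 13)   # z = 1.91
#' @export
compute_z <- function(observed, model, bsa = NULL, age = NULL) {
  stopifnot(inherits(model, "paedz_model"))
  require_covariates(model, bsa, age)
  mu <- model_mean(model, bsa, age)
  sigma <- model_rsd(model, bsa, age)
  z <- (observed - mu) / sigma
  tibble::tibble(
    measure = model$measure,
    observed = observed,
    predicted_mean = rep_len(mu, length(z)),
    rsd = rep_len(sigma, length(z)),
    z = z,
    centile = 100 * pnorm(z),
    out_of_range = abs(z) >= 2,
    hr_caution = model$measure %in% HR_DEPENDENT_MEASURES,
    out_of_envelope = !in_envelope(model, bsa, age, length(z))
  )
}

#' Measurement value at a given Z-score
#'
#' Inverts the Z-score equation: returns `mean + z * rsd` at the supplied
#' covariates, the exact algebraic inverse of [compute_z()].
#'
#' @param model A structural or functional model.
#' @param z Z-score(s).
#' @inheritParams compute_z
#' @return Measurement value(s) in the measure's native unit.
#' @export
invert_z <- function(model, z, bsa = NULL, age = NULL) {
  stopifnot(inherits(model, "paedz_model"))
  require_covariates(model, bsa, age)
  model_mean(model, bsa, age) + z * model_rsd(model, bsa, age)
}

#' Nomogram table of reference lines
#'
#' Evaluates the measurement values tracing the Z = -2, -1, 0, +1, +2 lines
#' (configurable) over a covariate grid; the tabular counterpart of the
#' published nomogram figures, and the source of truth for [plot_nomogram()].
#'
#' @param model A structural or functional model.
#' @param grid For a structural model, a data frame with columns `bsa` and
#'   `age`, or a numeric BSA vector with `age` fixed via the `age` argument.
#'   For a functional model, a numeric age vector or data frame with `age`.
#' @param z_lines Z levels to tabulate (default `-2:2`).
#' @param age Fixed age used when `grid` is a bare BSA vector (structural).
#'
#' @return A tibble with the grid covariates plus `z` and `value`, ordered by
#'   grid point then z; `value` is strictly increasing in `z` at every grid
#'   point because the regressed SD is positive.
#' @export
nomogram_table <- function(model, grid, z_lines = -2:2, age = NULL) {
  stopifnot(inherits(model, "paedz_model"))
  if (length(z_lines) == 0) abort("`z_lines` must be non-empty.")
  if (model$family == "structural") {
    if (is.numeric(grid)) {
      if (is.null(age)) abort("Provide `age` when `grid` is a BSA vector.")
      grid <- tibble::tibble(bsa = grid, age = age)
    }
    grid <- tibble::as_tibble(grid)
    if (!all(c("bsa", "age") %in% names(grid))) {
      abort("Structural nomogram grid needs `bsa` and `age` columns.")
    }
  } else if (model$family == "functional") {
    if (is.numeric(grid)) grid <- tibble::tibble(age = grid)
    grid <- tibble::as_tibble(grid)
    if (!"age" %in% names(grid)) abort("Functional nomogram grid needs an `age` column.")
  } else {
    abort("Nomograms are defined for structural and functional models only.")
  }
  if (nrow(grid) == 0) abort("Covariate grid is empty.")
  out <- tidyr::expand_grid(grid, z = sort(as.numeric(z_lines)))
  out$value <- invert_z(model, out$z, bsa = out[["bsa"]], age = out[["age"]])
  out
}
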