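#' I/O configuration for cohort tables
#'
#' Controls how [load_cohort()] maps and validates columns.
#'
#' @param bsa_formula BSA formula applied when `bsa` must be derived from
#'   height and weight.
#' @param aliases Named character vector mapping file column names to
#'   canonical names, e.g. `c(age = "chronological_age")`.
#' @param cm_columns Measure columns recorded in cm in the file; the loader
#'   converts them to mm (linear dimensions are stored in mm throughout).
#' @param age_range Expected chronological-age range; rows outside it raise a
#'   warning, not an error.
#' @return A list of class `io_config`.
#' @export
io_config <- function(bsa_formula = c("mosteller", "dubois", "haycock"),
                      aliases = character(), cm_columns = character(),
                      age_range = c(11, 18)) {
  structure(list(bsa_formula = match.arg(bsa_formula),
                 aliases = aliases, cm_columns = cm_columns,
                 age_range = age_range),
            class = "io_config")
}

covariate_cols <- c("athlete_id", "ethnicity", "chronological_age",
                    "biological_age", "height", "weight", "bsa", "heart_rate")

#' Default echocardiographic measure catalog
#'
#' Names, units and model family (structural, functional or lvef) for the
#' measures the package models by default. Linear dimensions in mm, LV mass
#' in g, volumes in mL, Doppler/TDI velocities in cm/s, DecT in ms, LVEF in
#' %, ratios dimensionless.
#'
#' @return A tibble with columns `measure`, `unit`, `family`.
#' @export
default_measure_catalog <- function() {
  tibble::tribble(
    ~measure,    ~unit,  ~family,
    "LVIDd",     "mm",   "structural",
    "IVSd",      "mm",   "structural",
    "PWTd",      "mm",   "structural",
    "LVM",       "g",    "structural",
    "LV_vol",    "mL",   "structural",
    "AoR",       "mm",   "structural",
    "LAD",       "mm",   "structural",
    "LA_vol",    "mL",   "structural",
    "E",         "cm/s", "functional",
    "A",         "cm/s", "functional",
    "E_A",       "",     "functional",
    "DecT",      "ms",   "functional",
    "septal_e",  "cm/s", "functional",
    "septal_a",  "cm/s", "functional",
    "lateral_e", "cm/s", "functional",
    "avg_E_e",   "",     "functional",
    "LVEF",      "%",    "lvef"
  )
}

#' Measure catalog of a cohort table
#'
#' The subset of the default catalog whose measures are present as columns
#' with at least one non-missing value; columns not in the default catalog
#' are included with unit `""` and family `NA`.
#'
#' @param cohort A cohort tibble as returned by [load_cohort()] or
#'   [simulate_cohort()].
#' @return A tibble with columns `measure`, `unit`, `family`.
#' @export
measure_catalog <- function(cohort) {
  meas <- setdiff(names(cohort), covariate_cols)
  meas <- meas[vapply(meas, function(m) any(!is.na(cohort[[m]])), logical(1))]
  cat0 <- default_measure_catalog()
  dplyr::bind_rows(
    dplyr::filter(cat0, .data$measure %in% meas),
    tibble::tibble(measure = setdiff(meas, cat0$measure),
                   unit = "", family = NA_character_)
  )
}

#' Read and validate a cohort table
#'
#' Reads a CSV/TSV file (one athlete per row), applies column aliases,
#' derives BSA from height and weight where absent, converts declared
#' cm columns to mm, and enforces the record invariants: unique
#' `athlete_id`, positive ages and BSA, strictly positive finite
#' measurements. Rows violating hard invariants are rejected with
#' row-indexed messages; missing optional fields stay `NA`, never zero.
#'
#' @param path Path to a CSV (or TSV, by `.tsv` extension) file with a
#'   header row.
#' @param config An [io_config()].
#' @return A validated cohort tibble.
#' @export
load_cohort <- function(path, config = io_config()) {
  if (!file.exists(path)) abort(sprintf("Cohort file '%s' does not exist.", path))
  reader <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) readr::read_tsv else readr::read_csv
  raw <- reader(path, col_types = readr::cols(.default = readr::col_character()),
                progress = FALSE)
  nm <- names(raw)
  hit <- nm %in% names(config$aliases)
  nm[hit] <- unname(config$aliases[nm[hit]])
  names(raw) <- nm

  mandatory <- c("athlete_id", "ethnicity", "chronological_age")
  missing_cols <- setdiff(mandatory, names(raw))
  if (length(missing_cols)) {
    abort(sprintf("Cohort file is missing mandatory column(s): %s.",
                  paste(missing_cols, collapse = ", ")))
  }
  if (!("bsa" %in% names(raw)) && !all(c("height", "weight") %in% names(raw))) {
    abort("Cohort file must contain either `bsa` or both `height` and `weight`.")
  }

  numeric_cols <- setdiff(names(raw), c("athlete_id", "ethnicity"))
  for (col in numeric_cols) {
    vals <- raw[[col]]
    parsed <- suppressWarnings(as.numeric(vals))
    bad <- which(!is.na(vals) & vals != "" & is.na(parsed))
    if (length(bad)) {
      abort(sprintf("Non-numeric value '%s' in row %d, column %s.",
                    vals[bad[1]], bad[1], col))
    }
    raw[[col]] <- parsed
  }

  for (col in setdiff(covariate_cols, names(raw))) raw[[col]] <- NA_real_
  cohort <- dplyr::relocate(raw, dplyr::all_of(covariate_cols))
  cohort$ethnicity <- tolower(cohort$ethnicity)

  if (anyDuplicated(cohort$athlete_id)) {
    abort(sprintf("Duplicate athlete_id: %s.",
                  cohort$athlete_id[anyDuplicated(cohort$athlete_id)]))
  }
  bad_age <- which(!is.na(cohort$chronological_age) & cohort$chronological_age <= 0)
  if (length(bad_age)) {
    abort(sprintf("Non-positive chronological_age in row %d.", bad_age[1]))
  }
  outside <- which(cohort$chronological_age < config$age_range[1] |
                   cohort$chronological_age > config$age_range[2])
  if (length(outside)) {
    warn(sprintf("%d row(s) have chronological_age outside [%g, %g] (kept).",
                 length(outside), config$age_range[1], config$age_range[2]))
  }

  derive <- is.na(cohort$bsa) & !is.na(cohort$height) & !is.na(cohort$weight)
  if (any(derive)) {
    cohort$bsa[derive] <- compute_bsa(cohort$height[derive], cohort$weight[derive],
                                      config$bsa_formula)
  }
  # Supplied BSA must agree with the configured formula when height/weight
  # are also present.
  have_all <- !is.na(cohort$bsa) & !is.na(cohort$height) & !is.na(cohort$weight) & !derive
  if (any(have_all)) {
    expect <- compute_bsa(cohort$height[have_all], cohort$weight[have_all],
                          config$bsa_formula)
    off <- which(abs(cohort$bsa[have_all] - expect) > 1e-9)
    if (length(off)) {
      warn(sprintf("%d row(s) have supplied bsa inconsistent with %s(height, weight).",
                   length(off), config$bsa_formula))
    }
  }
  if (any(is.na(cohort$bsa))) {
    abort(sprintf("Row %d has no bsa and no height/weight to derive it.",
                  which(is.na(cohort$bsa))[1]))
  }
  if (any(cohort$bsa <= 0)) {
    abort(sprintf("Non-positive bsa in row %d.", which(cohort$bsa <= 0)[1]))
  }

  meas <- setdiff(names(cohort), covariate_cols)
  for (col in intersect(config$cm_columns, meas)) cohort[[col]] <- cohort[[col]] * 10
  for (col in meas) {
    bad <- which(!is.na(cohort[[col]]) &
                 (!is.finite(cohort[[col]]) | cohort[[col]] <= 0))
    if (length(bad)) {
      abort(sprintf("Measurement %s must be finite and positive; row %d is not.",
                    col, bad[1]))
    }
  }
  cohort
}

#' Write a cohort table to CSV
#'
#' Numeric fields are written at full precision so
#' `load_cohort(write_cohort(x))` round-trips exactly.
#'
#' @param cohort A cohort tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  readr::write_csv(cohort, path, progress = FALSE)
  invisible(path)
}

#' Write fitted models to a coefficient file
#'
#' Serialises a list of `paedz` models to JSON, one object per measure with
#' fields `measure`, `family`, `unit`, `bsa_formula`, `mean_form`,
#' `coefficients`, `rsd_coefficients` and `n_fit`, so a coefficient file is
#' self-describing (including which BSA formula its covariates assume).
#'
#' @param models A list of `paedz` model objects (or [fit_structural()]-style
#'   fit reports, whose `$model` is taken).
#' @param path Output JSON path.
#' @param n_fit Optional integer vector of fitting sample sizes.
#' @return `path`, invisibly.
#' @export
write_models <- function(models, path, n_fit = NULL) {
  if (inherits(models, "paedz_model") || inherits(models, "paedz_fit")) {
    models <- list(models)
  }
  objs <- purrr::map2(models, seq_along(models), function(m, i) {
    n <- NA_integer_
    if (inherits(m, "paedz_fit")) {
      n <- m$n
      m <- m$model
    }
    if (!is.null(n_fit)) n <- n_fit[[i]]
    co <- as.list(model_coefs(m))
    mean_names <- switch(m$family, structural = c("a", "b", "c"),
                         functional = c("a", "b", "c"), lvef = "mean")
    rsd_names <- switch(m$family, structural = c("d", "e", "f"),
                        functional = c("d", "e"), lvef = "sd")
    list(measure = m$measure, family = m$family, unit = m$unit,
         bsa_formula = m$bsa_formula %||% NA,
         mean_form = m$mean_form %||% NA,
         coefficients = co[mean_names], rsd_coefficients = co[rsd_names],
         n_fit = n)
  })
  jsonlite::write_json(unname(objs), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}

#' Read a coefficient file
#'
#' Inverse of [write_models()]; reconstructs validated model objects.
#'
#' @param path JSON coefficient file.
#' @return A named list of `paedz` model objects (names are measures).
#' @export
read_models <- function(path) {
  objs <- jsonlite::read_json(path, simplifyVector = FALSE)
  models <- purrr::map(objs, function(o) {
    co <- o$coefficients
    rs <- o$rsd_coefficients
    switch(o$family,
      structural = structural_model(o$measure, a = co$a, b = co$b, c = co$c,
                                    d = rs$d, e = rs$e, f = rs$f,
                                    mean_form = o$mean_form, unit = o$unit %||% "mm",
                                    bsa_formula = o$bsa_formula %||% "mosteller"),
      functional = functional_model(o$measure, a = co$a, b = co$b, c = co$c,
                                    d = rs$d, e = rs$e, unit = o$unit %||% "cm/s"),
      lvef       = lvef_model(co$mean, rs$sd),
      abort(sprintf("Unknown model family '%s' in %s.", o$family, path))
    )
  })
  names(models) <- purrr::map_chr(models, "measure")
  models
}
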