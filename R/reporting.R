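#' Nomogram plot of a normative model
#'
#' Draws the reference chart: measurement against BSA (structural) or
#' chronological age (functional), with the conventional line styles --
#' solid mean, dashed Z = +/-1, solid Z = +/-2. An optional cohort is
#' overlaid as points.
#'
#' @param model A structural or functional model.
#' @param cohort Optional cohort tibble to overlay.
#' @param age Fixed age for a structural nomogram (default: midpoint of the
#'   validity envelope), since the chart has BSA on the x-axis.
#' @param n_grid Number of grid points along the x-axis.
#' @return A ggplot object.
#' @export
plot_nomogram <- function(model, cohort = NULL, age = NULL, n_grid = 100) {
  stopifnot(inherits(model, "paedz_model"))
  if (model$family == "structural") {
    age <- age %||% mean(ENVELOPE$age)
    grid <- tibble::tibble(
      bsa = seq(ENVELOPE$bsa[1], ENVELOPE$bsa[2], length.out = n_grid),
      age = age)
    xvar <- "bsa"
    xlab <- expression(BSA ~ (m^2))
  } else if (model$family == "functional") {
    grid <- tibble::tibble(
      age = seq(ENVELOPE$age[1], ENVELOPE$age[2], length.out = n_grid))
    xvar <- "age"
    xlab <- "Chronological age (years)"
  } else {
    abort("Nomograms are defined for structural and functional models only.")
  }
  tab <- nomogram_table(model, grid)
  tab$line <- factor(abs(tab$z), levels = c(0, 1, 2),
                     labels = c("Z = 0", "Z = ±1", "Z = ±2"))
  p <- ggplot2::ggplot(tab, ggplot2::aes(x = .data[[xvar]], y = .data$value,
                                         group = .data$z)) +
    ggplot2::geom_line(ggplot2::aes(colour = .data$line,
                                    linetype = .data$line)) +
    ggplot2::scale_linetype_manual(
      values = c("Z = 0" = "solid", "Z = ±1" = "dashed",
                 "Z = ±2" = "solid"), name = NULL) +
    ggplot2::scale_colour_manual(
      values = c("Z = 0" = "#2c5aa0", "Z = ±1" = "#2c5aa0",
                 "Z = ±2" = "#b2182b"), name = NULL) +
    ggplot2::labs(x = xlab,
                  y = sprintf("%s%s", model$measure,
                              if (nzchar(model$unit)) paste0(" (", model$unit, ")") else ""),
                  title = sprintf("%s nomogram", model$measure)) +
    ggplot2::theme_minimal()
  if (!is.null(cohort) && model$measure %in% names(cohort)) {
    pts <- tibble::tibble(
      x = if (xvar == "bsa") cohort$bsa else cohort$chronological_age,
      y = cohort[[model$measure]],
      ethnicity = cohort$ethnicity)
    p <- p + ggplot2::geom_point(
      data = pts,
      ggplot2::aes(x = .data$x, y = .data$y, shape = .data$ethnicity),
      inherit.aes = FALSE, alpha = 0.4, size = 1)
  }
  p
}

#' @rdname plot_nomogram
#' @param object A model (autoplot interface).
#' @param ... Passed to [plot_nomogram()].
#' @method autoplot structural_model
#' @export
autoplot.structural_model <- function(object, ...) plot_nomogram(object, ...)

#' @rdname plot_nomogram
#' @method autoplot functional_model
#' @export
autoplot.functional_model <- function(object, ...) plot_nomogram(object, ...)

#' Write a nomogram as CSV (and optionally a plot)
#'
#' The CSV from [nomogram_table()] is the source of truth; the image is
#' derived from it and excluded from byte-stability expectations.
#'
#' @param model A structural or functional model.
#' @param grid Covariate grid as in [nomogram_table()].
#' @param csv_path Output CSV path.
#' @param plot_path Optional image path (written via [ggplot2::ggsave()]).
#' @param age Fixed age used when `grid` is a bare BSA vector.
#' @return The nomogram tibble, invisibly.
#' @export
write_nomogram <- function(model, grid, csv_path, plot_path = NULL, age = NULL) {
  tab <- nomogram_table(model, grid, age = age)
  readr::write_csv(tab, csv_path, progress = FALSE)
  if (!is.null(plot_path)) {
    ggplot2::ggsave(plot_path, plot_nomogram(model), width = 6, height = 4)
  }
  invisible(tab)
}

#' Longitudinal Z-score tracking for one athlete
#'
#' Serial echocardiograms re-expressed as Z-scores stay comparable while the
#' athlete grows; a stable z implies measurement tracking along the expected
#' allometric/age trajectory. Flags any visit with |z| >= 2 and any
#' between-visit z jump of at least `drift_threshold` (a screening
#' convenience, not a clinical rule).
#'
#' @param visits A data frame with one row per visit: `date` (sortable),
#'   `age`, `bsa`, `measure`, `observed`.
#' @param models Named list of `paedz` models (as from [read_models()]).
#' @param drift_threshold Absolute between-visit change in z that raises the
#'   drift flag (default 1.5).
#' @return A tibble ordered by measure then date with `z`, `out_of_range`,
#'   `drift_flag`, `out_of_envelope` columns.
#' @export
track_athlete <- function(visits, models, drift_threshold = 1.5) {
  visits <- tibble::as_tibble(visits)
  need <- c("date", "age", "measure", "observed")
  missing_cols <- setdiff(need, names(visits))
  if (length(missing_cols)) {
    abort(sprintf("`visits` is missing column(s): %s.",
                  paste(missing_cols, collapse = ", ")))
  }
  if (nrow(visits) == 0) abort("At least one visit is required.")
  if (inherits(models, "paedz_model")) models <- setNames(list(models), models$measure)
  visits |>
    dplyr::group_by(.data$measure) |>
    dplyr::arrange(.data$date, .by_group = TRUE) |>
    dplyr::group_modify(function(d, key) {
      m <- models[[key$measure]]
      if (is.null(m)) {
        abort(sprintf("No model supplied for measure '%s'.", key$measure))
      }
      zr <- compute_z(d$observed, m, bsa = d[["bsa"]], age = d$age)
      d$z <- zr$z
      d$centile <- zr$centile
      d$out_of_range <- zr$out_of_range
      d$out_of_envelope <- zr$out_of_envelope
      if (any(d$out_of_envelope)) {
        warn(sprintf("%d visit(s) for '%s' fall outside the model's validity envelope.",
                     sum(d$out_of_envelope), key$measure))
      }
      d$drift_flag <- c(FALSE, abs(diff(d$z)) >= drift_threshold)
      d
    }) |>
    dplyr::ungroup()
}
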