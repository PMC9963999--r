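# Published worked-example models used across the suite.
ivsd_model <- function(mean_form = "additive_age") {
  structural_model("IVSd", a = 6.055, b = -0.020, c = 0.031,
                   d = 1.100, e = 0.062, f = -0.008, mean_form = mean_form)
}

eeprime_model <- function() {
  functional_model("avg_E_e", a = 0.009, b = -0.418, c = 10.485,
                   d = 1.413, e = -0.025, unit = "")
}

# Minimal three-athlete cohort with covariates and two measures.
tiny_cohort <- function() {
  tibble::tibble(
    athlete_id = c("a1", "a2", "a3"),
    ethnicity = c("arab", "arab", "black"),
    chronological_age = c(12, 14.5, 17),
    biological_age = c(13, 15.5, 18.2),
    height = c(150, 165, 178),
    weight = c(40, 55, 70),
    bsa = compute_bsa(c(150, 165, 178), c(40, 55, 70)),
    heart_rate = c(80, 72, 65),
    IVSd = c(6.1, 7.0, 8.2),
    avg_E_e = c(6.5, 6.1, 5.8)
  )
}

write_tiny_csv <- function(path, drop = NULL, mutate_fn = identity) {
  df <- mutate_fn(tiny_cohort())
  df <- df[, setdiff(names(df), drop)]
  readr::write_csv(df, path, progress = FALSE)
  path
}
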