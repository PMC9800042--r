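#' Group-wise median targets for the synthetic cohort
#'
#' Default calibration targets for the synthetic generator: one median per
#' clinical feature for the normal (CACS < threshold) and elevated
#' (CACS >= threshold) groups. The default pattern has the elevated group
#' older, with larger waist, higher triglycerides and HbA1c, and lower HDL,
#' cholesterol and LDL — the structure typical of a cardiac-screening
#' cohort. `null_feature_medians()` gives both groups the same (marginal)
#' medians, producing a zero-signal cohort in which the label is
#' independent of every feature; useful as a negative control.
#'
#' @return A tibble with columns `feature`, `normal`, `elevated`.
#' @examples
#' default_feature_medians()
#' @export
default_feature_medians <- function() {
  tibble::tribble(
    ~feature,        ~normal, ~elevated,
    "age",              54.0,      61.0,
    "height",          179.0,     178.0,
    "weight",           86.0,      87.0,
    "waist",            96.0,     101.0,
    "cholesterol",     230.0,     224.0,
    "triglycerides",   122.0,     136.0,
    "hdl",              53.0,      49.0,
    "ldl",             158.0,     152.0,
    "hba1c",             5.4,       5.6
  )
}

#' @rdname default_feature_medians
#' @export
null_feature_medians <- function() {
  m <- c(age = 57, height = 179, weight = 87, waist = 98,
         cholesterol = 228, triglycerides = 129, hdl = 51, ldl = 156,
         hba1c = 5.5)
  tibble::tibble(feature = names(m), normal = unname(m),
                 elevated = unname(m))
}

#' Per-feature spread parameters for the synthetic cohort
#'
#' Standard deviations (on the log scale for triglycerides, which are drawn
#' log-normally) chosen as typical within-group dispersions for an adult
#' cardiac-screening population.
#'
#' @return Named numeric vector, one entry per clinical feature.
#' @export
default_dispersion <- function() {
  c(age = 9, height = 7, weight = 15, waist = 11, cholesterol = 40,
    triglycerides = 0.45, hdl = 13, ldl = 35, hba1c = 0.5)
}

#' Configuration for the synthetic two-institution cohort generator
#'
#' Bundles and validates every knob of [generate_cohort()]. The defaults
#' reproduce the study conditions the generator emulates: 1450 raw records
#' of which exactly 680 are complete, split 477/203 across two
#' institutions, with a 50/50 outcome balance at a CACS threshold of 5.
#' (The 477 + 203 default acknowledges an off-by-one: published per-site
#' sample sizes of 477 and 202 sum to 679, not 680; pass
#' `site_counts = c(477, 202)` with `n_complete = 679` to use them
#' verbatim.)
#'
#' @param n_total Number of raw records to generate.
#' @param n_complete Number of records with no missing field.
#' @param site_counts Complete-record count per institution; must sum to
#'   `n_complete`.
#' @param class_balance If `TRUE`, exactly `n_complete %/% 2` complete
#'   records are in the elevated class; otherwise labels are Bernoulli(1/2).
#' @param cacs_threshold CACS cutoff separating normal from elevated.
#' @param feature_medians Tibble as from [default_feature_medians()].
#' @param dispersion Named vector as from [default_dispersion()].
#' @param site_shift Additive location shift applied to institution 2's
#'   continuous features (0 = no systematic site difference, matching the
#'   near-identical per-site medians the generator is calibrated to).
#' @param p_male Probability a patient is male (the screening population is
#'   predominantly male; sex is label-independent by default).
#' @param p_zero_cacs Probability a normal-group patient has CACS exactly 0
#'   (the score is zero-inflated).
#' @param seed Integer seed; generation is bit-reproducible given the
#'   config.
#' @return A validated list of class `cohort_config`.
#' @examples
#' cfg <- cohort_config(seed = 42)
#' cfg$n_complete
#' @export
cohort_config <- function(n_total = 1450,
                          n_complete = 680,
                          site_counts = c(477, 203),
                          class_balance = TRUE,
                          cacs_threshold = 5,
                          feature_medians = default_feature_medians(),
                          dispersion = default_dispersion(),
                          site_shift = 0,
                          p_male = 0.8,
                          p_zero_cacs = 0.5,
                          seed = 1L) {
  cfg <- structure(
    list(n_total = as.integer(n_total),
         n_complete = as.integer(n_complete),
         site_counts = as.integer(site_counts),
         class_balance = isTRUE(class_balance),
         cacs_threshold = cacs_threshold,
         feature_medians = feature_medians,
         dispersion = dispersion,
         site_shift = site_shift,
         p_male = p_male,
         p_zero_cacs = p_zero_cacs,
         seed = as.integer(seed)),
    class = "cohort_config")
  validate_cohort_config(cfg)
  cfg
}

validate_cohort_config <- function(cfg) {
  if (cfg$n_complete > cfg$n_total) {
    abort("`n_complete` must not exceed `n_total`.",
          class = "fedforest_config_error")
  }
  if (sum(cfg$site_counts) != cfg$n_complete) {
    abort(sprintf(
      "`site_counts` (sum %d) must sum to `n_complete` (%d).",
      sum(cfg$site_counts), cfg$n_complete),
      class = "fedforest_config_error")
  }
  if (any(cfg$site_counts <= 0L)) {
    abort("every entry of `site_counts` must be positive.",
          class = "fedforest_config_error")
  }
  if (cfg$cacs_threshold <= 0) {
    abort("`cacs_threshold` must be positive.",
          class = "fedforest_config_error")
  }
  fm <- cfg$feature_medians
  need <- setdiff(CLINICAL_COLS, c("sex", "cacs"))
  if (!all(need %in% fm$feature)) {
    abort(paste0("`feature_medians` is missing features: ",
                 paste(setdiff(need, fm$feature), collapse = ", ")),
          class = "fedforest_config_error")
  }
  if (any(fm$normal <= 0) || any(fm$elevated <= 0)) {
    abort("all feature medians must be positive.",
          class = "fedforest_config_error")
  }
  if (!all(need %in% names(cfg$dispersion))) {
    abort("`dispersion` must name every clinical feature.",
          class = "fedforest_config_error")
  }
  invisible(cfg)
}

#' @export
print.cohort_config <- function(x, ...) {
  cat("<cohort_config>\n")
  cat(sprintf("  raw records: %d (complete: %d; sites: %s)\n",
              x$n_total, x$n_complete,
              paste(x$site_counts, collapse = " + ")))
  cat(sprintf("  CACS threshold: %s; balanced classes: %s; seed: %d\n",
              format(x$cacs_threshold), x$class_balance, x$seed))
  invisible(x)
}
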