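#' Complete-case filtering of a raw cohort
#'
#' Drops every row with at least one missing clinical field, preserving row
#' order. This is the default preprocessing path; see [impute_missing()]
#' for the mean/median imputation variant.
#'
#' @param cohort A schema-valid cohort tibble.
#' @param quiet Suppress the informational message with the dropped count.
#' @return The cohort restricted to complete rows.
#' @examples
#' cohort <- generate_cohort(cohort_config(seed = 42))
#' nrow(complete_case_filter(cohort)) # 680
#' @export
complete_case_filter <- function(cohort, quiet = FALSE) {
  check_cohort_schema(cohort)
  keep <- stats::complete.cases(cohort[, CLINICAL_COLS])
  out <- cohort[keep, , drop = FALSE]
  if (nrow(out) == 0L) {
    abort("no complete records remain after filtering; cannot train.",
          class = "fedforest_data_error")
  }
  if (!quiet) {
    inform(sprintf("complete-case filter: kept %d of %d records (%d dropped)",
                   nrow(out), nrow(cohort), nrow(cohort) - nrow(out)),
           class = "fedforest_info")
  }
  out
}

#' Impute missing clinical values per institution
#'
#' Replaces each missing numeric entry with the column mean or median
#' computed over the non-missing values of the *same institution's* rows:
#' in a federated setting no raw values may be pooled across sites, even
#' for imputation statistics. Missing `sex` entries are filled with the
#' site's modal sex. Originally present values are never altered.
#'
#' @param cohort A schema-valid cohort tibble.
#' @param strategy `"mean"` or `"median"`.
#' @return A cohort tibble with no missing clinical entries.
#' @examples
#' cohort <- generate_cohort(cohort_config(seed = 1))
#' imputed <- impute_missing(cohort, "median")
#' anyNA(imputed)
#' @export
impute_missing <- function(cohort, strategy = c("mean", "median")) {
  check_cohort_schema(cohort)
  strategy <- match.arg(strategy)
  stat <- if (strategy == "mean") {
    function(v) mean(v, na.rm = TRUE)
  } else {
    function(v) median(v, na.rm = TRUE)
  }
  num_cols <- setdiff(CLINICAL_COLS, "sex")
  for (col in num_cols) {
    if (all(is.na(cohort[[col]]))) {
      abort(sprintf("column '%s' is entirely missing; cannot impute.", col),
            class = "fedforest_data_error")
    }
  }
  n_filled <- 0L
  out <- cohort |>
    dplyr::group_by(.data$institution) |>
    dplyr::group_modify(function(g, key) {
      for (col in num_cols) {
        miss <- is.na(g[[col]])
        if (any(miss)) {
          if (all(miss)) {
            abort(sprintf(
              "column '%s' is entirely missing in institution %s.",
              col, key$institution), class = "fedforest_data_error")
          }
          g[[col]][miss] <- stat(g[[col]][!miss])
        }
      }
      miss_sex <- is.na(g$sex)
      if (any(miss_sex)) {
        tab <- sort(table(g$sex[!miss_sex]), decreasing = TRUE)
        g$sex[miss_sex] <- names(tab)[1]
      }
      g
    }) |>
    dplyr::ungroup()
  # group_modify reorders by group; restore the original row order
  out <- out[order(match(out$patient_id, cohort$patient_id)), ]
  n_filled <- sum(is.na(cohort[, CLINICAL_COLS])) -
    sum(is.na(out[, CLINICAL_COLS]))
  inform(sprintf("imputation (%s): filled %d missing entries", strategy,
                 n_filled), class = "fedforest_info")
  out[, COHORT_COLS]
}

#' Binarize the continuous CACS into elevated vs normal
#'
#' @param cohort A cohort tibble with no missing `cacs`.
#' @param threshold Score cutoff; a record is elevated (label 1) iff
#'   `cacs >= threshold` (boundary inclusive).
#' @return Integer vector of 0/1 labels.
#' @examples
#' binarize_cacs(tibble::tibble(cacs = c(0, 4.999, 5, 80)), 5)
#' @export
binarize_cacs <- function(cohort, threshold = 5) {
  if (threshold < 0) {
    abort("`threshold` must be non-negative.",
          class = "fedforest_config_error")
  }
  if (anyNA(cohort$cacs)) {
    abort("`cacs` contains missing values; filter or impute first.",
          class = "fedforest_data_error")
  }
  as.integer(cohort$cacs >= threshold)
}

#' Assemble per-institution model datasets
#'
#' Splits a complete cohort by institution and builds, for each site, the
#' numeric feature table actually used by the models: the eight predictors
#' `age, sex01, waist, cholesterol, triglycerides, hdl, ldl, hba1c` (sex
#' recoded M = 1, F = 0) plus the binary `label` from [binarize_cacs()].
#' Height and weight are cohort descriptors only and are dropped here.
#'
#' @param cohort A complete (no missing clinical fields) cohort tibble.
#' @param threshold CACS cutoff passed to [binarize_cacs()].
#' @param pool If `TRUE`, ignore the institution column and return a
#'   single pooled dataset (the centralized view of the data).
#' @return A tibble with one row per site: `institution`, `n`, and a
#'   list-column `data` of feature+label tibbles.
#' @examples
#' cohort <- complete_case_filter(generate_cohort(cohort_config(seed = 42)),
#'                                quiet = TRUE)
#' sites <- assemble_sites(cohort)
#' sites$n # 477 203
#' @export
assemble_sites <- function(cohort, threshold = 5, pool = FALSE) {
  check_cohort_schema(cohort)
  if (anyNA(cohort[, CLINICAL_COLS])) {
    abort("cohort has missing clinical fields; filter or impute first.",
          class = "fedforest_data_error")
  }
  bad_sex <- !cohort$sex %in% c("M", "F")
  if (any(bad_sex)) {
    abort(sprintf("unrecognized sex value '%s'", cohort$sex[bad_sex][1]),
          class = "fedforest_data_error")
  }
  if (any(is.na(cohort$institution))) {
    abort("unknown (missing) institution label.",
          class = "fedforest_data_error")
  }
  feat <- tibble::tibble(
    institution = if (pool) 0L else as.integer(cohort$institution),
    age = cohort$age,
    sex01 = as.numeric(cohort$sex == "M"),
    waist = cohort$waist,
    cholesterol = cohort$cholesterol,
    triglycerides = cohort$triglycerides,
    hdl = cohort$hdl,
    ldl = cohort$ldl,
    hba1c = cohort$hba1c,
    label = binarize_cacs(cohort, threshold)
  )
  feat |>
    tidyr::nest(data = -"institution") |>
    dplyr::mutate(n = purrr::map_int(.data$data, nrow)) |>
    dplyr::arrange(.data$institution) |>
    dplyr::select("institution", "n", "data")
}

#' Pool a multi-site dataset tibble into a single centralized site
#'
#' Concatenates every site's rows into one dataset, as if the data stemmed
#' from a single source. With a single input site the result is that site
#' unchanged (same institution label), which makes a one-site federation
#' structurally identical to the centralized model.
#'
#' @param sites A sites tibble from [assemble_sites()].
#' @return A one-row sites tibble.
#' @export
pool_sites <- function(sites) {
  check_sites(sites)
  if (nrow(sites) == 1L) return(sites)
  pooled <- dplyr::bind_rows(sites$data)
  tibble::tibble(institution = 0L, n = nrow(pooled), data = list(pooled))
}

check_sites <- function(sites) {
  if (!all(c("institution", "n", "data") %in% names(sites)) ||
      nrow(sites) == 0L) {
    abort("expected a non-empty sites tibble from `assemble_sites()`.",
          class = "fedforest_schema_error")
  }
  for (d in sites$data) {
    missing_cols <- setdiff(c(MODEL_FEATURES, "label"), names(d))
    if (length(missing_cols) > 0) {
      abort(paste0("site dataset lacks column(s): ",
                   paste(missing_cols, collapse = ", ")),
            class = "fedforest_schema_error")
    }
    if (nrow(d) == 0L) {
      abort("a site dataset is empty.", class = "fedforest_data_error")
    }
  }
  invisible(sites)
}
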