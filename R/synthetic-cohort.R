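#' Generate a synthetic two-institution clinical cohort
#'
#' Draws a raw cohort table whose preprocessed structure matches the
#' configured targets by construction: exactly `n_complete` of the
#' `n_total` records are complete, the complete records split across
#' institutions exactly as `site_counts`, and (with `class_balance`)
#' exactly half of them are in the elevated-CACS class. Features are drawn
#' label-first: the binary outcome is fixed, then each feature is sampled
#' independently from a location family (normal, or log-normal for
#' triglycerides and CACS) whose median equals the configured group target,
#' so empirical group medians concentrate around the calibration table.
#' Missingness is injected completely at random into exactly
#' `n_total - n_complete` rows (1–3 clinical fields each), which makes the
#' complete-case count deterministic rather than binomial.
#'
#' Height and weight are generated so the cohort table is a complete
#' clinical record, but they are not model features; BMI is derivable from
#' them and never stored.
#'
#' @param config A [cohort_config()].
#' @return A tibble with columns `patient_id`, `institution`, `age`, `sex`
#'   (`"M"`/`"F"`), `height`, `weight`, `waist`, `cholesterol`,
#'   `triglycerides`, `hdl`, `ldl`, `hba1c`, `cacs`, in that order.
#' @examples
#' cohort <- generate_cohort(cohort_config(seed = 42))
#' nrow(cohort)                      # 1450
#' sum(stats::complete.cases(cohort)) # 680
#' @export
generate_cohort <- function(config = cohort_config()) {
  validate_cohort_config(config)
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit({
    if (is.null(old_seed)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old_seed, envir = globalenv())
    }
  })
  set.seed(config$seed)

  n_sites <- length(config$site_counts)
  n_missing_rows <- config$n_total - config$n_complete

  # --- complete records: labels first, exact counts by construction ----
  n_elev <- if (config$class_balance) {
    config$n_complete %/% 2L
  } else {
    sum(rbinom(config$n_complete, 1L, 0.5))
  }
  elev_per_site <- largest_remainder(n_elev, config$site_counts)

  complete_rows <- purrr::map2(seq_len(n_sites), elev_per_site,
    function(s, ne) {
      ns <- config$site_counts[s]
      lab <- c(rep(1L, ne), rep(0L, ns - ne))
      draw_features(lab, s, config)
    })
  complete_tbl <- dplyr::bind_rows(complete_rows)

  # --- incomplete records: same mixture, then fields knocked out ------
  if (n_missing_rows > 0L) {
    miss_per_site <- largest_remainder(n_missing_rows, config$site_counts)
    miss_rows <- purrr::map2(seq_len(n_sites), miss_per_site,
      function(s, nm) {
        if (nm == 0L) return(NULL)
        lab <- rbinom(nm, 1L, 0.5)
        draw_features(lab, s, config)
      })
    miss_tbl <- dplyr::bind_rows(miss_rows)
    # 1-3 clinical fields per row set missing, uniform over fields
    for (i in seq_len(nrow(miss_tbl))) {
      k <- sample(1:3, 1L)
      for (col in sample(CLINICAL_COLS, k)) {
        miss_tbl[[col]][i] <- NA
      }
    }
    out <- dplyr::bind_rows(complete_tbl, miss_tbl)
  } else {
    out <- complete_tbl
  }

  # interleave complete and incomplete rows, then assign stable ids
  out <- out[sample.int(nrow(out)), , drop = FALSE]
  out$patient_id <- sprintf("P%05d", seq_len(nrow(out)))
  out[, COHORT_COLS]
}

# deterministic largest-remainder apportionment of `total` over `weights`
# (remainder ties go to the larger weight, then to the lower index)
largest_remainder <- function(total, weights) {
  quota <- total * weights / sum(weights)
  base <- floor(quota)
  rem <- total - sum(base)
  if (rem > 0) {
    ord <- order(-(quota - base), -weights, seq_along(weights))
    base[ord[seq_len(rem)]] <- base[ord[seq_len(rem)]] + 1
  }
  as.integer(base)
}

# draw one site's feature block conditional on the label vector
draw_features <- function(lab, site, config) {
  n <- length(lab)
  fm <- config$feature_medians
  disp <- config$dispersion
  shift <- if (site == 2L) config$site_shift else 0
  med_of <- function(feature) {
    row <- fm[fm$feature == feature, ]
    ifelse(lab == 1L, row$elevated, row$normal) + shift
  }
  draw_normal <- function(feature) {
    m <- med_of(feature)
    pmax(rnorm(n, mean = m, sd = disp[[feature]]), 0.05 * m)
  }
  draw_lognormal <- function(feature) {
    # median of a log-normal is exp(meanlog)
    rlnorm(n, meanlog = log(med_of(feature)), sdlog = disp[[feature]])
  }

  thr <- config$cacs_threshold
  cacs <- numeric(n)
  is_elev <- lab == 1L
  # zero-inflated below threshold; heavy-tailed log-normal excess above
  n_norm <- sum(!is_elev)
  if (n_norm > 0) {
    zero <- rbinom(n_norm, 1L, config$p_zero_cacs) == 1L
    sub <- thr * rbeta(n_norm, 2, 5)
    cacs[!is_elev] <- ifelse(zero, 0, sub)
  }
  if (any(is_elev)) {
    cacs[is_elev] <- thr + rlnorm(sum(is_elev), log(15 * thr), 1.2)
  }

  tibble::tibble(
    patient_id = NA_character_,
    institution = as.integer(site),
    age = draw_normal("age"),
    sex = ifelse(runif(n) < config$p_male, "M", "F"),
    height = draw_normal("height"),
    weight = draw_normal("weight"),
    waist = draw_normal("waist"),
    cholesterol = draw_normal("cholesterol"),
    triglycerides = draw_lognormal("triglycerides"),
    hdl = draw_normal("hdl"),
    ldl = draw_normal("ldl"),
    hba1c = draw_normal("hba1c"),
    cacs = cacs
  )
}

#' Read and write cohort CSV files
#'
#' The on-disk format is a plain comma-separated file with a header row,
#' UTF-8 encoding, columns in the fixed cohort order, sex encoded
#' `"M"`/`"F"`, and missing values as empty cells (`read_cohort()` can
#' additionally accept the literal string `"NA"` via `na_strings`).
#' Numeric values round-trip exactly.
#'
#' @param cohort A cohort tibble as produced by [generate_cohort()].
#' @param path File path.
#' @param na_strings Cell values interpreted as missing on read.
#' @return `write_cohort()` returns `path` invisibly; `read_cohort()`
#'   returns a cohort tibble.
#' @examples
#' path <- tempfile(fileext = ".csv")
#' cohort <- generate_cohort(cohort_config(n_total = 20, n_complete = 20,
#'                                         site_counts = c(14, 6), seed = 1))
#' write_cohort(cohort, path)
#' identical(read_cohort(path)$age, cohort$age)
#' @export
write_cohort <- function(cohort, path) {
  check_cohort_schema(cohort)
  readr::write_csv(cohort[, COHORT_COLS], path, na = "")
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path, na_strings = "") {
  hdr <- names(readr::read_csv(path, n_max = 0, col_types = readr::cols(),
                               show_col_types = FALSE))
  extra <- setdiff(hdr, COHORT_COLS)
  missing_cols <- setdiff(COHORT_COLS, hdr)
  if (length(extra) > 0) {
    abort(paste0("unknown cohort column(s): ", paste(extra, collapse = ", ")),
          class = "fedforest_parse_error")
  }
  if (length(missing_cols) > 0) {
    abort(paste0("missing cohort column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "fedforest_parse_error")
  }
  spec <- readr::cols(
    patient_id = readr::col_character(),
    institution = readr::col_integer(),
    sex = readr::col_character(),
    .default = readr::col_double()
  )
  out <- suppressWarnings(
    readr::read_csv(path, col_types = spec, na = na_strings,
                    show_col_types = FALSE))
  probs <- readr::problems(out)
  if (nrow(probs) > 0) {
    p <- probs[1, ]
    abort(sprintf(
      "parse error at row %d, column '%s': expected %s, got '%s'",
      p$row, hdr[p$col], p$expected, p$actual),
      class = "fedforest_parse_error")
  }
  out[, COHORT_COLS]
}

check_cohort_schema <- function(cohort, arg = "cohort") {
  missing_cols <- setdiff(COHORT_COLS, names(cohort))
  if (length(missing_cols) > 0) {
    abort(paste0("`", arg, "` lacks column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "fedforest_schema_error")
  }
  invisible(cohort)
}
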