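new_cv_report <- function(folds, n_splits, total_trees, n_repetitions,
                          seed) {
  structure(
    folds,
    class = c("cv_report", class(tibble::tibble())),
    cv_meta = list(n_splits = n_splits, total_trees = total_trees,
                   n_repetitions = n_repetitions, seed = seed))
}

cv_meta <- function(report) attr(report, "cv_meta")

#' Per-fold and per-model views of a cross-validation report
#'
#' `tidy()` returns the per-fold rows as a plain tibble (one row per
#' train/validate step). `glance()` aggregates to one row per model:
#' means of accuracy, sensitivity, specificity and ROC AUC over the folds
#' where they are defined, the number of folds, and how many folds had an
#' undefined (single-class) AUC. `summary()` prints the same table.
#'
#' @param x A `cv_report`.
#' @param ... Unused.
#' @method tidy cv_report
#' @export
tidy.cv_report <- function(x, ...) {
  tibble::as_tibble(unclass_report(x))
}

unclass_report <- function(x) {
  attr(x, "cv_meta") <- NULL
  class(x) <- class(tibble::tibble())
  x
}

#' @rdname tidy.cv_report
#' @method glance cv_report
#' @export
glance.cv_report <- function(x, ...) {
  tidy(x) |>
    dplyr::group_by(.data$model) |>
    dplyr::summarise(
      accuracy = mean(.data$accuracy, na.rm = TRUE),
      sensitivity = mean(.data$sensitivity, na.rm = TRUE),
      specificity = mean(.data$specificity, na.rm = TRUE),
      roc_auc = mean(.data$roc_auc, na.rm = TRUE),
      n_folds = dplyr::n(),
      n_undefined_auc = sum(is.na(.data$roc_auc)),
      mean_n_validate = mean(.data$n),
      .groups = "drop")
}

#' @export
summary.cv_report <- function(object, ...) {
  out <- glance(object)
  meta <- cv_meta(object)
  cat(sprintf(
    "Cross-validation report: %d splits/site, %d trees, %d repetition(s)\n",
    meta$n_splits, meta$total_trees, meta$n_repetitions))
  print(out, n = Inf)
  invisible(out)
}

#' @export
print.cv_report <- function(x, ...) {
  meta <- cv_meta(x)
  cat(sprintf("<cv_report> %d folds (%d splits/site, %d trees, seed %d)\n",
              nrow(x), meta$n_splits, meta$total_trees, meta$seed))
  print(tidy(x), ...)
  invisible(x)
}

#' Serialize a cross-validation report to JSON
#'
#' Layout: one object per model with, for each metric, its fold mean,
#' the per-fold values, and the count of folds where it was undefined;
#' plus the run configuration and seed for provenance.
#'
#' @param report A `cv_report`.
#' @param seed The experiment seed to echo into the file.
#' @return A JSON string.
#' @export
report_to_json <- function(report, seed = cv_meta(report)$seed) {
  folds <- tidy(report)
  metrics <- c("accuracy", "sensitivity", "specificity", "roc_auc")
  models <- split(folds, folds$model)
  body <- purrr::map(models, function(d) {
    purrr::map(setNames(metrics, metrics), function(m) {
      v <- d[[m]]
      list(mean = mean(v, na.rm = TRUE),
           per_fold = v,
           n_undefined = sum(is.na(v)))
    })
  })
  meta <- cv_meta(report)
  jsonlite::toJSON(
    list(models = body,
         config = list(n_splits = meta$n_splits,
                       total_trees = meta$total_trees,
                       n_repetitions = meta$n_repetitions),
         seed = seed),
    auto_unbox = TRUE, digits = NA, na = "null")
}

#' Plot the fold-level metric distributions of a report
#'
#' One panel per metric, one box per model, over the per-fold values
#' (undefined folds dropped).
#'
#' @param object A `cv_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot cv_report
#' @export
autoplot.cv_report <- function(object, ...) {
  long <- tidy(object) |>
    tidyr::pivot_longer(cols = c("accuracy", "sensitivity", "specificity",
                                 "roc_auc"),
                        names_to = "metric", values_to = "value") |>
    dplyr::filter(!is.na(.data$value))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$model, y = .data$value,
                                     fill = .data$model)) +
    ggplot2::geom_boxplot(outlier.size = 0.4, show.legend = FALSE) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "fold value",
                  title = "Cross-validated performance by model") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x =
                     ggplot2::element_text(angle = 30, hjust = 1))
}

#' Plot group-wise feature medians of a cohort
#'
#' Compares the empirical medians of each clinical feature between the
#' normal and elevated outcome groups of a complete cohort — the
#' structure the synthetic generator is calibrated to.
#'
#' @param cohort A complete cohort tibble.
#' @param threshold CACS cutoff.
#' @return A ggplot object.
#' @export
plot_cohort_medians <- function(cohort, threshold = 5) {
  lab <- binarize_cacs(cohort, threshold)
  num <- setdiff(CLINICAL_COLS, c("sex", "cacs"))
  long <- cohort |>
    dplyr::mutate(group = ifelse(lab == 1L, "elevated", "normal")) |>
    tidyr::pivot_longer(cols = dplyr::all_of(num), names_to = "feature",
                        values_to = "value") |>
    dplyr::group_by(.data$group, .data$feature) |>
    dplyr::summarise(median = median(.data$value), .groups = "drop")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$feature, y = .data$median,
                                     fill = .data$group)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_wrap(~feature, scales = "free") +
    ggplot2::labs(x = NULL, y = "group median",
                  title = "Cohort feature medians by outcome group") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
}
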