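# run expr under a temporary RNG state seeded with `seed`
with_local_seed <- function(seed, expr) {
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old_seed, envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

#' Even random splits of one site's data
#'
#' Randomly permutes the site's row indices and chunks them into
#' `n_splits` contiguous blocks whose sizes differ by at most one (the
#' first `n %% n_splits` blocks get the extra row). Splits are disjoint,
#' exhaustive, and unstratified.
#'
#' @param n Number of rows at the site.
#' @param n_splits Number of even splits.
#' @param seed Integer seed; the plan is deterministic given it.
#' @return List of `n_splits` integer index vectors.
#' @examples
#' lengths(make_splits(477, 10, seed = 1)) # seven 48s, three 47s
#' @export
make_splits <- function(n, n_splits = 10L, seed = 1L) {
  if (n < n_splits) {
    abort(sprintf("cannot make %d splits from %d rows.", n_splits, n),
          class = "fedforest_config_error")
  }
  perm <- with_local_seed(seed, sample.int(n))
  sizes <- rep(n %/% n_splits, n_splits)
  extra <- n %% n_splits
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  ends <- cumsum(sizes)
  starts <- c(1L, head(ends, -1L) + 1L)
  purrr::map2(starts, ends, ~ perm[.x:.y])
}

#' Per-site split plan for all-combinations cross-validation
#'
#' Each institution splits its own data into `n_splits` even parts with
#' its own derived seed; no indices ever refer to another site's rows.
#'
#' @param sites Sites tibble from [assemble_sites()].
#' @param n_splits Number of even splits per site.
#' @param seed Integer seed.
#' @return Tibble with columns `institution`, `split`, `idx`
#'   (list-column of row indices into that site's dataset).
#' @export
make_split_plan <- function(sites, n_splits = 10L, seed = 1L) {
  check_sites(sites)
  purrr::pmap_dfr(
    list(sites$institution, sites$n, seq_len(nrow(sites))),
    function(institution, n, s) {
      splits <- make_splits(n, n_splits, seed = derive_seed(seed, s))
      tibble::tibble(institution = institution,
                     split = seq_len(n_splits), idx = splits)
    })
}

#' Classification metrics with rank-based ROC AUC
#'
#' Elevated (label 1) is the positive class: sensitivity is the true
#' positive rate, specificity the true negative rate. The ROC AUC is the
#' Mann–Whitney rank statistic — the probability that a random elevated
#' patient scores above a random normal patient, with half credit for
#' ties. When the truth contains a single class, sensitivity or
#' specificity and the AUC are returned as `NA` (flagged, never coerced
#' to 0) and are excluded from report means.
#'
#' @param truth Binary 0/1 truth vector.
#' @param votes Binary 0/1 predicted classes.
#' @param scores Numeric scores in `[0, 1]` used for the AUC.
#' @return One-row tibble: `accuracy`, `sensitivity`, `specificity`,
#'   `roc_auc`, `n`.
#' @examples
#' compute_metrics(c(1, 1, 0, 0), c(1, 0, 0, 1),
#'                 scores = c(0.9, 0.4, 0.2, 0.6))
#' @export
compute_metrics <- function(truth, votes, scores) {
  stopifnot(length(truth) == length(votes),
            length(truth) == length(scores))
  truth <- as.integer(truth)
  votes <- as.integer(votes)
  n1 <- sum(truth == 1L)
  n0 <- sum(truth == 0L)
  acc <- mean(truth == votes)
  sens <- if (n1 > 0) sum(votes == 1L & truth == 1L) / n1 else NA_real_
  spec <- if (n0 > 0) sum(votes == 0L & truth == 0L) / n0 else NA_real_
  auc <- if (n1 > 0 && n0 > 0) {
    r <- rank(scores) # average ranks give ties half credit
    (sum(r[truth == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  } else {
    NA_real_
  }
  tibble::tibble(accuracy = acc, sensitivity = sens, specificity = spec,
                 roc_auc = auc, n = length(truth))
}

# shared engine for every CV variant: enumerate the Cartesian product of
# per-site splits, train via `trainer(train_sites, seed)`, validate on the
# union of the held-out splits
cv_engine <- function(sites, trainer, model, n_splits, n_repetitions,
                      seed) {
  check_sites(sites)
  k <- nrow(sites)
  reps <- purrr::map(seq_len(n_repetitions), function(rep) {
    plan <- make_split_plan(sites, n_splits, seed = derive_seed(seed, rep, 0))
    combos <- expand.grid(purrr::map(seq_len(k), ~ seq_len(n_splits)))
    names(combos) <- paste0("s", seq_len(k))
    purrr::map_dfr(seq_len(nrow(combos)), function(ci) {
      held <- as.integer(combos[ci, ])
      train_sites <- sites
      valid_parts <- vector("list", k)
      for (s in seq_len(k)) {
        idx <- plan$idx[plan$institution == sites$institution[s] &
                          plan$split == held[s]][[1]]
        d <- sites$data[[s]]
        train_sites$data[[s]] <- d[-idx, , drop = FALSE]
        train_sites$n[s] <- nrow(d) - length(idx)
        valid_parts[[s]] <- d[idx, , drop = FALSE]
      }
      valid <- dplyr::bind_rows(valid_parts)
      forest <- trainer(train_sites, seed = derive_seed(seed, rep, ci))
      pred <- forest_predict(forest, valid)
      m <- compute_metrics(valid$label, pred$vote, pred$score)
      dplyr::bind_cols(
        tibble::tibble(model = model, repetition = rep, combination = ci,
                       splits = paste(held, collapse = "/")),
        m)
    })
  })
  dplyr::bind_rows(reps)
}

#' All-combinations federated cross-validation
#'
#' Each institution makes `n_splits` even splits of its own data. Every
#' cross-site combination of held-out splits forms one validation fold:
#' the sites train local forests on their remaining splits, the forests
#' are merged into the global model, and the merged model is scored on
#' the union of the held-out splits. Two sites with ten splits each give
#' exactly 100 train/validate steps per repetition; repetitions redo the
#' whole procedure with fresh split plans (10 repetitions = 1000 recorded
#' runs).
#'
#' @param sites Sites tibble from [assemble_sites()].
#' @param n_splits Even splits per site.
#' @param total_trees Global ensemble size per fold.
#' @param hyperparams A [forest_hyperparams()].
#' @param n_repetitions Number of independent repetitions.
#' @param seed Integer seed; all fold and tree randomness derives from it.
#' @param weights Optional tree-allocation override (e.g. `c(2, 1)`);
#'   default allocates by the per-fold training sample counts.
#' @return A `cv_report` tibble with one row per fold.
#' @export
federated_cross_validate <- function(sites, n_splits = 10L,
                                     total_trees = 100L,
                                     hyperparams = forest_hyperparams(),
                                     n_repetitions = 10L, seed = 1L,
                                     weights = NULL) {
  trainer <- function(train_sites, seed) {
    federated_train(train_sites, total_trees = total_trees,
                    hyperparams = hyperparams, seed = seed,
                    weights = weights)
  }
  folds <- cv_engine(sites, trainer, "federated", n_splits,
                     n_repetitions, seed)
  new_cv_report(folds, n_splits = n_splits, total_trees = total_trees,
                n_repetitions = n_repetitions, seed = seed)
}

#' Centralized cross-validation on the same folds as the federation
#'
#' The centralized reference model is trained on the pooled data of all
#' sites. For an exact paired comparison it is evaluated on the *same*
#' validation unions as [federated_cross_validate()]: for each
#' combination of held-out splits, one forest is trained on all pooled
#' rows except those splits and scored on their union. With identical
#' seeds the folds match the federated run row for row.
#'
#' @inheritParams federated_cross_validate
#' @return A `cv_report` tibble.
#' @export
centralized_cross_validate <- function(sites, n_splits = 10L,
                                       total_trees = 100L,
                                       hyperparams = forest_hyperparams(),
                                       n_repetitions = 10L, seed = 1L) {
  trainer <- function(train_sites, seed) {
    centralized_train(train_sites, total_trees = total_trees,
                      hyperparams = hyperparams, seed = seed)
  }
  folds <- cv_engine(sites, trainer, "centralized", n_splits,
                     n_repetitions, seed)
  new_cv_report(folds, n_splits = n_splits, total_trees = total_trees,
                n_repetitions = n_repetitions, seed = seed)
}

#' Per-institution local baselines under their own cross-validation
#'
#' Each institution trains and evaluates on its own data alone via
#' ordinary `n_splits`-fold CV (the single-site degenerate case of the
#' all-combinations scheme), using the full `total_trees` ensemble size.
#'
#' @inheritParams federated_cross_validate
#' @return A `cv_report` with models `"local_<institution>"`.
#' @export
local_cross_validate <- function(sites, n_splits = 10L, total_trees = 100L,
                                 hyperparams = forest_hyperparams(),
                                 n_repetitions = 10L, seed = 1L) {
  check_sites(sites)
  folds <- purrr::map_dfr(seq_len(nrow(sites)), function(s) {
    one <- sites[s, ]
    trainer <- function(train_sites, seed) {
      federated_train(train_sites, total_trees = total_trees,
                      hyperparams = hyperparams, seed = seed)
    }
    cv_engine(one, trainer, paste0("local_", one$institution),
              n_splits, n_repetitions, seed = derive_seed(seed, 1000 + s))
  })
  new_cv_report(folds, n_splits = n_splits, total_trees = total_trees,
                n_repetitions = n_repetitions, seed = seed)
}

#' Run the full multi-model experiment
#'
#' Generates (or takes) a cohort, preprocesses it (complete-case by
#' default, or per-site mean/median imputation), assembles the site
#' datasets, and evaluates the requested model variants: each
#' institution's local model, the federated merged model, and the pooled
#' centralized reference — the federated and centralized runs paired on
#' identical validation folds. Optionally writes the report as JSON and a
#' summary CSV, plus the global federated forest trained on the full
#' data, into `out_dir`.
#'
#' @param cohort Raw cohort tibble; generated from `config` when `NULL`.
#' @param config A [cohort_config()] used when `cohort` is `NULL` (its
#'   seed also seeds generation).
#' @param models Subset of `c("local", "federated", "centralized")`.
#' @param threshold CACS cutoff for the binary outcome.
#' @param impute `"none"` (complete-case), `"mean"` or `"median"`.
#' @param n_splits,total_trees,n_repetitions,hyperparams,weights,seed As
#'   in [federated_cross_validate()].
#' @param out_dir Optional output directory for report files.
#' @return (Invisibly) a list with `report` (the combined `cv_report`),
#'   `summary` (per-model means), `forest` (global federated forest on
#'   the full preprocessed data), and `n_preprocessed`.
#' @export
run_experiment <- function(cohort = NULL, config = cohort_config(),
                           models = c("local", "federated", "centralized"),
                           threshold = 5, impute = c("none", "mean",
                                                     "median"),
                           n_splits = 10L, total_trees = 100L,
                           n_repetitions = 10L,
                           hyperparams = forest_hyperparams(),
                           weights = NULL, seed = 1L, out_dir = NULL) {
  impute <- match.arg(impute)
  models <- match.arg(models, several.ok = TRUE)
  if (is.null(cohort)) cohort <- generate_cohort(config)
  check_cohort_schema(cohort)
  prepped <- if (impute == "none") {
    complete_case_filter(cohort)
  } else {
    impute_missing(cohort, impute)
  }
  sites <- assemble_sites(prepped, threshold = threshold)

  parts <- list()
  if ("local" %in% models && nrow(sites) > 1L) {
    parts$local <- local_cross_validate(
      sites, n_splits, total_trees, hyperparams, n_repetitions,
      seed = derive_seed(seed, 1))
  }
  if ("federated" %in% models) {
    parts$federated <- federated_cross_validate(
      sites, n_splits, total_trees, hyperparams, n_repetitions,
      seed = derive_seed(seed, 2), weights = weights)
  }
  if ("centralized" %in% models) {
    parts$centralized <- centralized_cross_validate(
      sites, n_splits, total_trees, hyperparams, n_repetitions,
      seed = derive_seed(seed, 2))
  }
  report <- new_cv_report(dplyr::bind_rows(parts),
                          n_splits = n_splits, total_trees = total_trees,
                          n_repetitions = n_repetitions, seed = seed)
  forest <- federated_train(sites, total_trees = total_trees,
                            hyperparams = hyperparams,
                            seed = derive_seed(seed, 3),
                            weights = weights)
  out <- list(report = report, summary = glance(report), forest = forest,
              n_preprocessed = nrow(prepped))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    writeLines(report_to_json(report, seed = seed),
               file.path(out_dir, "metrics.json"), useBytes = TRUE)
    readr::write_csv(out$summary, file.path(out_dir, "summary.csv"))
    write_forest(forest, file.path(out_dir, "global_forest.json"))
    inform(sprintf("experiment outputs written to %s", out_dir),
           class = "fedforest_info")
  }
  invisible(out)
}
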