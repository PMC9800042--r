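#' Apportion ensemble trees across sites
#'
#' Largest-remainder apportionment of `total_trees` proportional to the
#' site weights (typically sample counts): each site first receives the
#' floor of its exact quota `total_trees * w_k / sum(w)`, then the
#' leftover trees go to the sites with the largest fractional remainders,
#' ties resolved toward the larger weight and then the lower site index.
#' Every site is guaranteed at least one tree.
#'
#' Note the 2:1 convention: a two-site federation weighted `c(2, 1)`
#' yields the 67/33 split, while weighting by the actual sample counts
#' `c(477, 202)` yields 70/30.
#'
#' @param total_trees Total size of the global ensemble.
#' @param site_weights Positive weight per site.
#' @return Integer vector of per-site tree counts summing to
#'   `total_trees`.
#' @examples
#' allocate_trees(100, c(2, 1))     # 67 33
#' allocate_trees(100, c(477, 202)) # 70 30
#' @export
allocate_trees <- function(total_trees, site_weights) {
  if (any(site_weights <= 0)) {
    abort("`site_weights` must all be positive.",
          class = "fedforest_config_error")
  }
  k <- length(site_weights)
  if (total_trees < k) {
    abort("`total_trees` must be at least the number of sites.",
          class = "fedforest_config_error")
  }
  counts <- largest_remainder(total_trees, site_weights)
  # guarantee every site >= 1 tree, taking from the largest allocation
  while (any(counts == 0L)) {
    counts[which.max(counts)] <- counts[which.max(counts)] - 1L
    counts[which(counts == 0L)[1]] <- 1L
  }
  counts
}

#' Merge locally trained forests into one global forest
#'
#' Concatenates the tree lists in the order given, preserving per-tree
#' provenance; no tree is modified. All forests must share hyperparameters
#' and the feature schema. Merging is associative.
#'
#' @param forests List of `fed_forest` objects.
#' @return A `fed_forest` whose size is the sum of the input sizes.
#' @export
merge_forests <- function(forests) {
  forests <- forests[purrr::map_int(forests, ~ length(.x$trees)) > 0L]
  if (length(forests) == 0L) {
    abort("nothing to merge: all forests are empty.",
          class = "fedforest_data_error")
  }
  ref <- forests[[1]]
  for (f in forests[-1]) {
    if (!identical(f$features, ref$features)) {
      abort("cannot merge forests with different feature schemas.",
            class = "fedforest_schema_error")
    }
    same <- identical(
      f$hyperparams[c("mtry", "min_leaf", "max_depth", "bootstrap",
                      "feature_mode", "score", "criterion")],
      ref$hyperparams[c("mtry", "min_leaf", "max_depth", "bootstrap",
                        "feature_mode", "score", "criterion")])
    if (!same) {
      abort("cannot merge forests with different hyperparameters.",
            class = "fedforest_schema_error")
    }
  }
  hp <- ref$hyperparams
  hp$n_trees <- sum(purrr::map_int(forests, ~ length(.x$trees)))
  new_forest(purrr::flatten(purrr::map(forests, "trees")),
             unlist(purrr::map(forests, "provenance")), hp)
}

#' Train a federated random forest across sites
#'
#' The federated mechanism: the global ensemble size is apportioned across
#' sites by [allocate_trees()] (by sample count, or by an explicit
#' `weights` override such as `c(2, 1)`), each site trains its share of
#' trees strictly on its own data, and the local forests are merged into
#' one global model. No raw record crosses a site boundary — only the
#' fitted trees do. With a single site this reduces exactly to
#' [train_local_forest()] on that site (same derived seed), which is also
#' how the centralized baseline is computed.
#'
#' @param sites Sites tibble from [assemble_sites()].
#' @param total_trees Global ensemble size.
#' @param hyperparams A [forest_hyperparams()].
#' @param seed Integer seed; site `k` trains under `derive_seed(seed, k)`
#'   so the result is independent of training order.
#' @param weights Optional allocation weight override (default: per-site
#'   sample counts).
#' @return A `fed_forest` with per-tree site provenance.
#' @examples
#' cohort <- complete_case_filter(generate_cohort(cohort_config(seed = 42)),
#'                                quiet = TRUE)
#' sites <- assemble_sites(cohort)
#' f <- federated_train(sites, total_trees = 10, seed = 1,
#'                      weights = c(2, 1))
#' table(f$provenance)
#' @export
federated_train <- function(sites, total_trees = 100L,
                            hyperparams = forest_hyperparams(),
                            seed = 1L, weights = NULL) {
  check_sites(sites)
  if (is.null(weights)) weights <- sites$n
  if (length(weights) != nrow(sites)) {
    abort("`weights` must have one entry per site.",
          class = "fedforest_config_error")
  }
  counts <- allocate_trees(total_trees, weights)
  locals <- purrr::pmap(
    list(sites$data, sites$institution, counts, seq_len(nrow(sites))),
    function(data, institution, n_trees, k) {
      train_local_forest(data, n_trees = n_trees,
                         hyperparams = hyperparams,
                         seed = derive_seed(seed, k),
                         institution = institution)
    })
  merge_forests(locals)
}

#' Train the centralized reference forest
#'
#' Pools every site's rows into one dataset — as if the data stemmed from
#' a single source — and trains one forest of `total_trees` trees on it.
#' Implemented as the degenerate one-site federation on the pooled data,
#' so a single-site federated model and the centralized model are
#' bit-identical given the same seed.
#'
#' @inheritParams federated_train
#' @return A `fed_forest`.
#' @export
centralized_train <- function(sites, total_trees = 100L,
                              hyperparams = forest_hyperparams(),
                              seed = 1L) {
  federated_train(pool_sites(sites), total_trees = total_trees,
                  hyperparams = hyperparams, seed = seed)
}
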