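#' Random-forest hyperparameters
#'
#' The split criterion is always gini impurity. Defaults follow the
#' canonical random-forest recipe: bootstrap resampling per tree,
#' unlimited depth, leaves down to a single sample, and `mtry = 4`
#' candidate features drawn fresh at every split from the eight model
#' features. `feature_mode = "per_tree"` instead draws one 4-feature
#' subspace per tree and uses it at every split of that tree.
#'
#' @param n_trees Number of trees in a (local) forest.
#' @param mtry Number of candidate features per split.
#' @param min_leaf Minimum samples in each child of a split.
#' @param max_depth Maximum tree depth (`Inf` = unlimited; a depth-0 tree
#'   is a single leaf).
#' @param bootstrap Draw a bootstrap resample per tree?
#' @param feature_mode `"per_split"` (standard mtry semantics) or
#'   `"per_tree"` (random-subspace variant).
#' @param score `"vote"`: a forest's score for a row is the fraction of
#'   trees voting elevated; `"fraction"`: the mean of leaf elevated-class
#'   fractions.
#' @return A list of class `forest_hyperparams`.
#' @export
forest_hyperparams <- function(n_trees = 100L, mtry = 4L, min_leaf = 1L,
                               max_depth = Inf, bootstrap = TRUE,
                               feature_mode = c("per_split", "per_tree"),
                               score = c("vote", "fraction")) {
  stopifnot(n_trees >= 1, mtry >= 1, min_leaf >= 1, max_depth >= 0)
  structure(list(n_trees = as.integer(n_trees), mtry = as.integer(mtry),
                 min_leaf = as.integer(min_leaf), max_depth = max_depth,
                 bootstrap = isTRUE(bootstrap),
                 feature_mode = match.arg(feature_mode),
                 score = match.arg(score), criterion = "gini"),
            class = "forest_hyperparams")
}

#' Gini impurity of a two-class node
#'
#' `1 - p0^2 - p1^2` over the class proportions: 0 for a pure node,
#' maximal 0.5 at equal counts.
#'
#' @param counts Length-2 non-negative vector `(n_normal, n_elevated)`.
#' @return Impurity in `[0, 0.5]`.
#' @examples
#' gini_impurity(c(10, 0)) # 0
#' gini_impurity(c(5, 5))  # 0.5
#' gini_impurity(c(3, 1))  # 0.375
#' @export
gini_impurity <- function(counts) {
  if (length(counts) != 2L || any(counts < 0)) {
    abort("`counts` must be two non-negative class counts.")
  }
  n <- sum(counts)
  if (n == 0) abort("cannot compute impurity of an empty node.")
  p <- counts / n
  1 - sum(p^2)
}

#' Best axis-aligned split over a set of candidate features
#'
#' Enumerates, for every candidate feature, all midpoints between
#' consecutive distinct sorted values, and returns the cut minimizing the
#' child-count-weighted mean gini impurity. Ties are broken
#' deterministically toward the lowest feature index, then the lowest
#' threshold. Rows go left iff `value <= threshold`.
#'
#' @param features Numeric data frame or matrix of feature columns.
#' @param labels Binary 0/1 vector.
#' @param candidates Column indices eligible for splitting.
#' @param min_leaf Minimum rows required in each child.
#' @return A one-row tibble with `feature`, `threshold`, `impurity`, or
#'   `NULL` if no split reduces impurity.
#' @examples
#' best_split(data.frame(x = 1:4), c(0, 0, 1, 1), candidates = 1)
#' @export
best_split <- function(features, labels, candidates, min_leaf = 1L) {
  X <- as.matrix(features)
  storage.mode(X) <- "double"
  if (length(candidates) == 0L) {
    abort("`candidates` must name at least one feature column.")
  }
  if (nrow(X) < 2L) {
    abort("need at least two samples to split.")
  }
  res <- .best_split_cpp(X, as.integer(labels),
                         as.integer(candidates) - 1L,
                         as.integer(min_leaf))
  if (!res$found) return(NULL)
  tibble::tibble(feature = res$feature + 1L, threshold = res$threshold,
                 impurity = res$impurity)
}

#' Grow a single gini decision tree
#'
#' Recursively partitions the dataset. At each node a fresh uniform draw
#' of `mtry` features (without replacement) forms the candidate set;
#' recursion stops at purity, `min_leaf`, `max_depth`, or when no split
#' reduces impurity. Leaves store the class counts of the training rows
#' they received.
#'
#' @param data Tibble with the eight model feature columns and a `label`
#'   column (see [assemble_sites()]).
#' @param hyperparams A [forest_hyperparams()]; `n_trees` is ignored here.
#' @param seed Integer seed for the tree's private random stream
#'   (bootstrap draw and per-split feature draws).
#' @return A `fed_tree` object.
#' @examples
#' d <- tibble::tibble(age = c(40, 45, 60, 65), sex01 = 1, waist = 95,
#'                     cholesterol = 220, triglycerides = 120, hdl = 50,
#'                     ldl = 150, hba1c = 5.5, label = c(0, 0, 1, 1))
#' tree <- grow_tree(d, forest_hyperparams(bootstrap = FALSE), seed = 1)
#' tree_predict(tree, d)
#' @export
grow_tree <- function(data, hyperparams = forest_hyperparams(), seed = 1L) {
  xy <- extract_xy(data)
  nodes <- .grow_tree_cpp(
    xy$X, xy$y, hyperparams$mtry, hyperparams$min_leaf,
    if (is.finite(hyperparams$max_depth)) {
      as.integer(hyperparams$max_depth)
    } else -1L,
    hyperparams$bootstrap, hyperparams$feature_mode == "per_tree",
    as.numeric(seed))
  structure(list(nodes = nodes, features = MODEL_FEATURES),
            class = "fed_tree")
}

extract_xy <- function(data) {
  missing_cols <- setdiff(c(MODEL_FEATURES, "label"), names(data))
  if (length(missing_cols) > 0) {
    abort(paste0("dataset lacks column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "fedforest_schema_error")
  }
  if (nrow(data) == 0L) {
    abort("empty dataset.", class = "fedforest_data_error")
  }
  X <- as.matrix(data[, MODEL_FEATURES])
  storage.mode(X) <- "double"
  list(X = X, y = as.integer(data$label))
}

#' Predict with a single decision tree
#'
#' Traverses by "value <= threshold goes left". The vote is the majority
#' class of the reached leaf's training counts (ties go to class 0,
#' normal); the fraction is the leaf's elevated-class share.
#'
#' @param tree A `fed_tree`.
#' @param newdata Tibble (or data frame) containing the eight model
#'   feature columns.
#' @return Tibble with one row per input row: `vote` (0/1) and
#'   `fraction` in `[0, 1]`.
#' @export
tree_predict <- function(tree, newdata) {
  X <- as.matrix(newdata[, tree$features])
  storage.mode(X) <- "double"
  nd <- tree$nodes
  res <- .predict_tree_cpp(nd$feature, nd$threshold, nd$left, nd$right,
                           nd$n0, nd$n1, X)
  tibble::tibble(vote = res$vote, fraction = res$frac)
}

#' Train a random forest on one site's local data
#'
#' Grows `n_trees` trees, each on a bootstrap resample of the site's data
#' (unless `bootstrap` is off), with an independent per-tree random stream
#' spawned from `seed` via [derive_seed()], so the forest is reproducible
#' regardless of training order. Every tree carries the site label as
#' provenance.
#'
#' @param data One site's feature+label tibble.
#' @param n_trees Number of trees.
#' @param hyperparams A [forest_hyperparams()].
#' @param seed Integer seed for this forest.
#' @param institution Site label recorded as per-tree provenance.
#' @return A `fed_forest` object.
#' @examples
#' cohort <- complete_case_filter(generate_cohort(cohort_config(seed = 42)),
#'                                quiet = TRUE)
#' sites <- assemble_sites(cohort)
#' f <- train_local_forest(sites$data[[1]], n_trees = 5, seed = 7,
#'                         institution = sites$institution[[1]])
#' f
#' @export
train_local_forest <- function(data, n_trees = 100L,
                               hyperparams = forest_hyperparams(),
                               seed = 1L, institution = 1L) {
  if (nrow(data) == 0L) {
    abort("empty dataset.", class = "fedforest_data_error")
  }
  hyperparams$n_trees <- as.integer(n_trees)
  trees <- purrr::map(seq_len(n_trees), function(t) {
    grow_tree(data, hyperparams, seed = derive_seed(seed, t))
  })
  new_forest(trees, rep(as.integer(institution), n_trees), hyperparams)
}

new_forest <- function(trees, provenance, hyperparams) {
  stopifnot(length(trees) == length(provenance))
  structure(list(trees = trees, provenance = as.integer(provenance),
                 hyperparams = hyperparams, features = MODEL_FEATURES),
            class = "fed_forest")
}

#' Forest prediction by majority vote
#'
#' The score of a row is the unweighted mean of the per-tree elevated
#' votes (or of leaf fractions under `score = "fraction"`); the forest
#' votes elevated iff the score exceeds 1/2, so a tied 0.5 goes to the
#' normal class.
#'
#' @param forest A `fed_forest`.
#' @param newdata Tibble containing the eight model feature columns.
#' @return Tibble with `score` in `[0, 1]` and `vote` (0/1) per row.
#' @export
forest_predict <- function(forest, newdata) {
  if (length(forest$trees) == 0L) {
    abort("empty forest.", class = "fedforest_data_error")
  }
  per_tree <- purrr::map(forest$trees, tree_predict, newdata = newdata)
  col <- if (forest$hyperparams$score == "vote") "vote" else "fraction"
  mat <- vapply(per_tree, function(p) as.numeric(p[[col]]),
                numeric(nrow(newdata)))
  score <- rowMeans(matrix(mat, nrow = nrow(newdata)))
  tibble::tibble(score = score, vote = as.integer(score > 0.5))
}

#' @export
predict.fed_forest <- function(object, newdata, ...) {
  forest_predict(object, newdata)
}

#' @export
print.fed_forest <- function(x, ...) {
  tab <- table(x$provenance)
  cat(sprintf("<fed_forest> %d trees (provenance: %s)\n",
              length(x$trees),
              paste(sprintf("site %s: %d", names(tab), tab),
                    collapse = ", ")))
  cat(sprintf("  mtry = %d, criterion = %s, bootstrap = %s, score = %s\n",
              x$hyperparams$mtry, x$hyperparams$criterion,
              x$hyperparams$bootstrap, x$hyperparams$score))
  invisible(x)
}

tree_depth <- function(tree) {
  nd <- tree$nodes
  depth_of <- function(i) {
    if (nd$feature[i + 1L] < 0L) return(0L)
    1L + max(depth_of(nd$left[i + 1L]), depth_of(nd$right[i + 1L]))
  }
  depth_of(0L)
}

root_feature <- function(tree) {
  f <- tree$nodes$feature[1]
  if (f < 0L) NA_character_ else tree$features[f + 1L]
}

#' Tidy a fitted forest into a per-tree summary
#'
#' @param x A `fed_forest`.
#' @param ... Unused.
#' @return One row per tree: provenance site, node/leaf counts, depth, and
#'   the feature used at the root split.
#' @method tidy fed_forest
#' @export
tidy.fed_forest <- function(x, ...) {
  tibble::tibble(
    tree = seq_along(x$trees),
    provenance = x$provenance,
    n_nodes = purrr::map_int(x$trees, ~ length(.x$nodes$feature)),
    n_leaves = purrr::map_int(x$trees, ~ sum(.x$nodes$feature < 0L)),
    depth = purrr::map_int(x$trees, tree_depth),
    root_feature = purrr::map_chr(x$trees, root_feature)
  )
}

#' @rdname tidy.fed_forest
#' @method glance fed_forest
#' @export
glance.fed_forest <- function(x, ...) {
  tibble::tibble(
    n_trees = length(x$trees),
    n_sites = length(unique(x$provenance)),
    mtry = x$hyperparams$mtry,
    bootstrap = x$hyperparams$bootstrap,
    criterion = x$hyperparams$criterion,
    median_depth = median(purrr::map_int(x$trees, tree_depth))
  )
}
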