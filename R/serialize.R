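#' Serialize forests to and from JSON
#'
#' A forest is exchanged between sites as a JSON document — the only
#' "model parameters" that ever cross institutional boundaries. The
#' schema is
#' `{"features": [...], "hyperparams": {...}, "trees": [{"provenance":
#' site, "root": node}, ...]}` with
#' `node = {"feature": i, "threshold": t, "left": node, "right": node}`
#' (feature indices 1-based into `features`) or `{"counts": [n0, n1]}`
#' for a leaf. Thresholds are written at full precision, so a round trip
#' preserves predictions bit-exactly.
#'
#' @param forest A `fed_forest`.
#' @param path File path for [write_forest()] / [read_forest()].
#' @return `forest_to_json()` a JSON string; `forest_from_json()` and
#'   `read_forest()` a `fed_forest`; `write_forest()` `path`, invisibly.
#' @examples
#' d <- tibble::tibble(age = c(40, 65), sex01 = 1, waist = 95,
#'                     cholesterol = 220, triglycerides = 120, hdl = 50,
#'                     ldl = 150, hba1c = 5.5, label = c(0, 1))
#' f <- train_local_forest(d, n_trees = 2, seed = 1)
#' identical(forest_to_json(forest_from_json(forest_to_json(f))),
#'           forest_to_json(f))
#' @export
forest_to_json <- function(forest) {
  hp <- forest$hyperparams
  hp$max_depth <- if (is.finite(hp$max_depth)) hp$max_depth else -1
  payload <- list(
    features = forest$features,
    hyperparams = unclass(hp),
    trees = purrr::map2(forest$trees, forest$provenance, function(tr, pv) {
      list(provenance = pv, root = node_to_list(tr$nodes, 0L))
    })
  )
  jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA, null = "null")
}

node_to_list <- function(nd, i) {
  k <- i + 1L
  if (nd$feature[k] < 0L) {
    # counts kept as an array even after auto_unbox
    list(counts = I(c(nd$n0[k], nd$n1[k])))
  } else {
    list(feature = nd$feature[k] + 1L,
         threshold = nd$threshold[k],
         left = node_to_list(nd, nd$left[k]),
         right = node_to_list(nd, nd$right[k]))
  }
}

#' @rdname forest_to_json
#' @export
forest_from_json <- function(json) {
  payload <- jsonlite::fromJSON(json, simplifyVector = FALSE)
  for (key in c("features", "hyperparams", "trees")) {
    if (is.null(payload[[key]])) {
      abort(sprintf("forest JSON lacks '%s'.", key),
            class = "fedforest_parse_error")
    }
  }
  features <- unlist(payload$features)
  if (!identical(features, MODEL_FEATURES)) {
    abort("forest JSON feature schema does not match the model features.",
          class = "fedforest_schema_error")
  }
  hp <- payload$hyperparams
  hyperparams <- forest_hyperparams(
    n_trees = hp$n_trees, mtry = hp$mtry, min_leaf = hp$min_leaf,
    max_depth = if (hp$max_depth < 0) Inf else hp$max_depth,
    bootstrap = hp$bootstrap, feature_mode = hp$feature_mode,
    score = hp$score)
  trees <- purrr::map(payload$trees, function(tr) {
    structure(list(nodes = list_to_nodes(tr$root), features = features),
              class = "fed_tree")
  })
  provenance <- purrr::map_int(payload$trees, ~ as.integer(.x$provenance))
  new_forest(trees, provenance, hyperparams)
}

# depth-first flattening mirroring node_to_list
list_to_nodes <- function(node) {
  flat <- new.env(parent = emptyenv())
  flat$feature <- integer()
  flat$threshold <- numeric()
  flat$left <- integer()
  flat$right <- integer()
  flat$n0 <- integer()
  flat$n1 <- integer()
  add <- function(nl) {
    i <- length(flat$feature)
    flat$feature[i + 1L] <- -1L
    flat$threshold[i + 1L] <- NA_real_
    flat$left[i + 1L] <- -1L
    flat$right[i + 1L] <- -1L
    flat$n0[i + 1L] <- 0L
    flat$n1[i + 1L] <- 0L
    if (!is.null(nl$counts)) {
      cts <- unlist(nl$counts)
      if (length(cts) != 2L || any(cts < 0)) {
        abort("corrupt forest JSON: bad leaf counts.",
              class = "fedforest_parse_error")
      }
      flat$n0[i + 1L] <- as.integer(cts[1])
      flat$n1[i + 1L] <- as.integer(cts[2])
    } else {
      f <- as.integer(nl$feature) - 1L
      if (is.na(f) || f < 0L) {
        abort("corrupt forest JSON: bad internal node.",
              class = "fedforest_parse_error")
      }
      l <- add(nl$left)
      r <- add(nl$right)
      flat$feature[i + 1L] <- f
      flat$threshold[i + 1L] <- as.numeric(nl$threshold)
      flat$left[i + 1L] <- l
      flat$right[i + 1L] <- r
    }
    i
  }
  add(node)
  list(feature = flat$feature, threshold = flat$threshold,
       left = flat$left, right = flat$right, n0 = flat$n0, n1 = flat$n1)
}

#' @rdname forest_to_json
#' @export
write_forest <- function(forest, path) {
  writeLines(forest_to_json(forest), path, useBytes = TRUE)
  invisible(path)
}

#' @rdname forest_to_json
#' @export
read_forest <- function(path) {
  forest_from_json(paste(readLines(path, warn = FALSE), collapse = "\n"))
}
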