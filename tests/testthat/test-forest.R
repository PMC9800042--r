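test_that("gini impurity matches hand calculations and bounds", {
  expect_equal(gini_impurity(c(10, 0)), 0)
  expect_equal(gini_impurity(c(5, 5)), 0.5)
  expect_equal(gini_impurity(c(3, 1)), 0.375)
  expect_error(gini_impurity(c(0, 0)))
  expect_error(gini_impurity(c(-1, 2)))
  for (c0 in 0:6) {
    for (c1 in 0:6) {
      if (c0 + c1 == 0) next
      g <- gini_impurity(c(c0, c1))
      expect_gte(g, 0)
      expect_lte(g, 0.5)
    }
  }
})

test_that("best_split solves the textbook instance and edge cases", {
  s <- best_split(data.frame(x = c(1, 2, 3, 4)), c(0, 0, 1, 1),
                  candidates = 1)
  expect_equal(s$feature, 1L)
  expect_equal(s$threshold, 2.5)
  expect_equal(s$impurity, 0)

  expect_null(best_split(data.frame(x = c(1, 2, 3)), c(1, 1, 1),
                         candidates = 1))
  # constant feature: no cut point exists
  expect_null(best_split(data.frame(x = c(2, 2, 2, 2)), c(0, 1, 0, 1),
                         candidates = 1))
  expect_error(best_split(data.frame(x = 1:4), c(0, 0, 1, 1),
                          candidates = integer(0)))
  expect_error(best_split(data.frame(x = 1), 0, candidates = 1))
})

test_that("best_split agrees with exhaustive search on random instances", {
  for (case in 1:40) {
    n <- 2 + (case * 7) %% 49
    p <- 1 + case %% 8
    inst <- withr::with_seed(1000 + case, {
      list(X = matrix(round(rnorm(n * p), 2), nrow = n),
           y = rbinom(n, 1, 0.5),
           cand = sort(sample.int(p, 1 + case %% p)))
    })
    got <- best_split(inst$X, inst$y, inst$cand)
    want <- brute_best_split(inst$X, inst$y, inst$cand)
    if (is.null(want)) {
      expect_null(got)
    } else {
      expect_false(is.null(got))
      expect_equal(got$impurity, want$impurity, tolerance = 1e-10)
      expect_equal(got$feature, want$feature)
      expect_equal(got$threshold, want$threshold)
    }
  }
})

test_that("grow_tree handles degenerate and separable data", {
  # mtry = 8 makes every feature a candidate, so the informative split is
  # found deterministically on the toy set
  hp <- forest_hyperparams(bootstrap = FALSE, mtry = 8)

  pure <- toy_separable()[1:2, ]
  t1 <- grow_tree(pure, hp, seed = 1)
  expect_equal(length(t1$nodes$feature), 1L)
  expect_equal(t1$nodes$feature[1], -1L)

  sep <- toy_separable()
  t2 <- grow_tree(sep, hp, seed = 1)
  p <- tree_predict(t2, sep)
  expect_equal(p$vote, sep$label)
  # depth 1: a single split on age is enough
  expect_equal(length(t2$nodes$feature), 3L)
  expect_equal(t2$nodes$feature[1] + 1L, which(MODEL_FEATURES() == "age"))

  t3 <- grow_tree(sep, hp, seed = 1)
  expect_identical(t2, t3)
  t4 <- grow_tree(sep, forest_hyperparams(bootstrap = TRUE), seed = 99)
  expect_s3_class(t4, "fed_tree")
})

test_that("leaf counts conserve the training set without bootstrap", {
  d <- random_model_data(60, seed = 21)
  tr <- grow_tree(d, forest_hyperparams(bootstrap = FALSE), seed = 5)
  nd <- tr$nodes
  leaves <- nd$feature < 0L
  expect_equal(sum(nd$n0[leaves] + nd$n1[leaves]), nrow(d))
  # unbounded depth + unique rows: perfect training accuracy
  expect_equal(tree_predict(tr, d)$vote, d$label)
})

test_that("tree prediction follows leaf counts, ties and boundaries", {
  leaf_only <- structure(
    list(nodes = list(feature = -1L, threshold = NA_real_, left = -1L,
                      right = -1L, n0 = 0L, n1 = 7L),
         features = MODEL_FEATURES()),
    class = "fed_tree")
  d <- toy_separable()[1, ]
  p <- tree_predict(leaf_only, d)
  expect_equal(p$vote, 1L)
  expect_equal(p$fraction, 1)

  tie <- leaf_only
  tie$nodes$n0 <- 3L
  tie$nodes$n1 <- 3L
  p2 <- tree_predict(tie, d)
  expect_equal(p2$vote, 0L) # ties are conservative: normal class
  expect_equal(p2$fraction, 0.5)

  # depth-1 stump on feature 1 at 2.5: the boundary value routes left
  stump <- structure(
    list(nodes = list(feature = c(0L, -1L, -1L),
                      threshold = c(2.5, NA, NA),
                      left = c(1L, -1L, -1L), right = c(2L, -1L, -1L),
                      n0 = c(2L, 2L, 0L), n1 = c(2L, 0L, 2L)),
         features = MODEL_FEATURES()),
    class = "fed_tree")
  row <- d
  row$age <- 2.5
  expect_equal(tree_predict(stump, row)$vote, 0L)
  row$age <- 2.500001
  expect_equal(tree_predict(stump, row)$vote, 1L)
})

test_that("local forests are deterministic with per-tree streams", {
  d <- random_model_data(50, seed = 31)
  f1 <- train_local_forest(d, n_trees = 67, seed = 12, institution = 1L)
  expect_equal(length(f1$trees), 67L)
  expect_true(all(f1$provenance == 1L))

  f2 <- train_local_forest(d, n_trees = 67, seed = 12, institution = 1L)
  expect_identical(forest_to_json(f1), forest_to_json(f2))
  f3 <- train_local_forest(d, n_trees = 67, seed = 13, institution = 1L)
  expect_false(identical(forest_to_json(f1), forest_to_json(f3)))

  # degenerate forest: one tree, no bootstrap == grow_tree on full data
  hp <- forest_hyperparams(bootstrap = FALSE)
  g1 <- train_local_forest(d, n_trees = 1, hyperparams = hp, seed = 4)
  g2 <- grow_tree(d, hp, seed = derive_seed(4, 1))
  expect_identical(g1$trees[[1]], g2)

  expect_error(train_local_forest(d[0, ], n_trees = 1),
               class = "fedforest_data_error")
})

test_that("per-tree feature subspace mode restricts splits to 4 features", {
  d <- random_model_data(80, seed = 41, p_signal = 1.5)
  hp <- forest_hyperparams(feature_mode = "per_tree", bootstrap = FALSE)
  tr <- grow_tree(d, hp, seed = 2)
  used <- unique(tr$nodes$feature[tr$nodes$feature >= 0L])
  expect_lte(length(used), 4L)
})

test_that("JSON serialization round-trips predictions bit-exactly", {
  d <- random_model_data(60, seed = 51, p_signal = 1)
  f <- train_local_forest(d, n_trees = 10, seed = 3, institution = 2L)
  json <- forest_to_json(f)
  back <- forest_from_json(json)
  expect_identical(forest_to_json(back), json)
  probe <- random_model_data(40, seed = 52)
  expect_identical(forest_predict(f, probe), forest_predict(back, probe))
  expect_identical(back$provenance, f$provenance)

  path <- withr::local_tempfile(fileext = ".json")
  write_forest(f, path)
  expect_identical(forest_to_json(read_forest(path)), json)

  expect_error(forest_from_json("{\"trees\": []}"),
               class = "fedforest_parse_error")
})

test_that("forest summaries expose provenance and structure", {
  d <- random_model_data(50, seed = 61)
  f <- train_local_forest(d, n_trees = 5, seed = 1, institution = 2L)
  td <- tidy(f)
  expect_equal(nrow(td), 5L)
  expect_true(all(td$provenance == 2L))
  expect_true(all(td$n_leaves == (td$n_nodes + 1) / 2))
  expect_true(all(td$root_feature %in% MODEL_FEATURES()))
  g <- glance(f)
  expect_equal(g$n_trees, 5L)
  expect_equal(g$criterion, "gini")
})
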