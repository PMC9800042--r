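test_that("tree allocation reproduces the printed apportionments", {
  expect_equal(allocate_trees(100, c(2, 1)), c(67L, 33L))
  expect_equal(allocate_trees(10, c(5, 5)), c(5L, 5L))
  expect_equal(allocate_trees(100, c(477, 202)), c(70L, 30L))
  expect_equal(allocate_trees(99, c(1, 1, 1)), c(33L, 33L, 33L))
  expect_error(allocate_trees(2, c(1, 1, 1)),
               class = "fedforest_config_error")
  expect_error(allocate_trees(10, c(1, 0)),
               class = "fedforest_config_error")
})

test_that("allocation sums exactly and is monotone in a site's weight", {
  for (case in 1:30) {
    inst <- withr::with_seed(2000 + case, {
      k <- 2 + case %% 4
      list(total = k + (case * 13) %% 200,
           w = runif(k, 0.1, 10))
    })
    counts <- allocate_trees(inst$total, inst$w)
    expect_equal(sum(counts), inst$total)
    expect_true(all(counts >= 1L))
    # raising one site's weight never lowers its count
    w2 <- inst$w
    w2[1] <- w2[1] * 1.7
    counts2 <- allocate_trees(inst$total, w2)
    expect_gte(counts2[1], counts[1])
  }
})

test_that("merging concatenates trees and conserves provenance", {
  d1 <- random_model_data(40, seed = 71)
  d2 <- random_model_data(30, seed = 72)
  f1 <- train_local_forest(d1, n_trees = 67, seed = 1, institution = 1L)
  f2 <- train_local_forest(d2, n_trees = 33, seed = 2, institution = 2L)
  merged <- merge_forests(list(f1, f2))
  expect_equal(length(merged$trees), 100L)
  expect_equal(as.vector(table(merged$provenance)), c(67L, 33L))
  expect_identical(merged$trees[[1]], f1$trees[[1]])
  expect_identical(merged$trees[[68]], f2$trees[[1]])

  # associativity (on serialized form)
  f3 <- train_local_forest(d1, n_trees = 5, seed = 3, institution = 3L)
  a <- merge_forests(list(merge_forests(list(f1, f2)), f3))
  b <- merge_forests(list(f1, merge_forests(list(f2, f3))))
  expect_identical(forest_to_json(a), forest_to_json(b))

  # empty forest is a merge identity
  empty <- fedforest:::new_forest(list(), integer(0), f1$hyperparams)
  expect_identical(forest_to_json(merge_forests(list(f1, empty))),
                   forest_to_json(f1))

  f_bad <- train_local_forest(d2, n_trees = 2, seed = 1,
                              hyperparams = forest_hyperparams(mtry = 2))
  expect_error(merge_forests(list(f1, f_bad)),
               class = "fedforest_schema_error")
})

test_that("merged-forest votes equal the brute-force union vote", {
  d1 <- random_model_data(40, seed = 81, p_signal = 1)
  d2 <- random_model_data(25, seed = 82, p_signal = 1)
  f1 <- train_local_forest(d1, n_trees = 7, seed = 4, institution = 1L)
  f2 <- train_local_forest(d2, n_trees = 5, seed = 5, institution = 2L)
  merged <- merge_forests(list(f1, f2))
  probe <- random_model_data(30, seed = 83)
  got <- forest_predict(merged, probe)
  want <- brute_forest_vote(c(f1$trees, f2$trees), probe)
  expect_equal(got$score, want$score)
  expect_equal(got$vote, want$vote)
})

test_that("forest voting applies the mean-vote score and 0.5 tie rule", {
  d <- toy_separable()
  hp <- forest_hyperparams(bootstrap = FALSE, mtry = 8)
  f <- train_local_forest(d, n_trees = 4, hyperparams = hp, seed = 1)
  p <- forest_predict(f, d)
  expect_equal(p$score, as.numeric(d$label)) # all trees agree
  expect_equal(p$vote, d$label)

  # two single-leaf trees voting 1 and 0: score 0.5 -> vote 0
  leaf <- function(n0, n1) {
    structure(list(nodes = list(feature = -1L, threshold = NA_real_,
                                left = -1L, right = -1L,
                                n0 = n0, n1 = n1),
                   features = MODEL_FEATURES()),
              class = "fed_tree")
  }
  tie_forest <- fedforest:::new_forest(list(leaf(0L, 5L), leaf(5L, 0L)),
                                       c(1L, 2L), hp)
  pt <- forest_predict(tie_forest, d[1, ])
  expect_equal(pt$score, 0.5)
  expect_equal(pt$vote, 0L)

  expect_error(forest_predict(
    fedforest:::new_forest(list(), integer(0), hp), d),
    class = "fedforest_data_error")
})

test_that("federated training allocates, trains locally, and merges", {
  sites <- small_sites(seed = 10)
  f <- federated_train(sites, total_trees = 100, seed = 6,
                       weights = c(2, 1))
  expect_equal(as.vector(table(f$provenance)), c(67L, 33L))
  # proportional default: 80:40 -> 67:33 at total 100
  f2 <- federated_train(sites, total_trees = 99, seed = 6)
  expect_equal(sum(f2$provenance == 1L), 66L)
  expect_equal(sum(f2$provenance == 2L), 33L)

  # three equal sites, 99 trees: 33 each
  d <- sites$data[[1]]
  three <- tibble::tibble(institution = 1:3, n = nrow(d),
                          data = list(d, d, d))
  f3 <- federated_train(three, total_trees = 99, seed = 1)
  expect_equal(as.vector(table(f3$provenance)), c(33L, 33L, 33L))
})

test_that("one-site federation equals local and centralized training", {
  sites <- small_sites(seed = 12)
  one <- sites[2, ]
  fed <- federated_train(one, total_trees = 20, seed = 9)
  loc <- train_local_forest(one$data[[1]], n_trees = 20,
                            seed = derive_seed(9, 1),
                            institution = one$institution)
  cen <- centralized_train(one, total_trees = 20, seed = 9)
  expect_identical(forest_to_json(fed), forest_to_json(loc))
  expect_identical(forest_to_json(fed), forest_to_json(cen))
})

test_that("training touches only each site's own rows", {
  sites <- small_sites(seed = 13)
  seen <- list()
  local_mocked_bindings(
    train_local_forest = function(data, n_trees = 100L,
                                  hyperparams = forest_hyperparams(),
                                  seed = 1L, institution = 1L) {
      seen[[length(seen) + 1]] <<- list(institution = institution,
                                        data = data)
      f <- fedforest:::new_forest(list(), integer(0), hyperparams)
      f$trees <- list()
      f
    },
    .package = "fedforest"
  )
  try(federated_train(sites, total_trees = 30, seed = 2), silent = TRUE)
  expect_equal(length(seen), 2L)
  for (s in seq_along(seen)) {
    site_row <- sites[sites$institution == seen[[s]]$institution, ]
    expect_identical(seen[[s]]$data, site_row$data[[1]])
  }
})
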