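# Independent brute-force oracles and tiny fixtures, used to cross-check
# the package implementations on small instances.

# exhaustive best-split search: every feature x every midpoint cut
brute_best_split <- function(X, y, candidates, min_leaf = 1L) {
  X <- as.matrix(X)
  n <- nrow(X)
  gini <- function(cls) {
    if (length(cls) == 0) return(0)
    p <- mean(cls == 1)
    1 - p^2 - (1 - p)^2
  }
  parent <- gini(y)
  best <- NULL
  for (f in sort(candidates)) {
    vals <- sort(unique(X[, f]))
    if (length(vals) < 2) next
    for (k in seq_len(length(vals) - 1)) {
      thr <- (vals[k] + vals[k + 1]) / 2
      left <- X[, f] <= thr
      nl <- sum(left); nr <- n - nl
      if (nl < min_leaf || nr < min_leaf) next
      g <- (nl * gini(y[left]) + nr * gini(y[!left])) / n
      if (is.null(best) || g < best$impurity - 1e-12) {
        best <- list(feature = f, threshold = thr, impurity = g)
      }
    }
  }
  if (!is.null(best) && best$impurity < parent - 1e-12) best else NULL
}

# ROC AUC by explicit pair counting with half credit for ties
brute_auc <- function(truth, scores) {
  pos <- scores[truth == 1]
  neg <- scores[truth == 0]
  if (length(pos) == 0 || length(neg) == 0) return(NA_real_)
  total <- 0
  for (p in pos) {
    for (q in neg) {
      total <- total + if (p > q) 1 else if (p == q) 0.5 else 0
    }
  }
  total / (length(pos) * length(neg))
}

# majority vote over an explicit union of tree lists
brute_forest_vote <- function(trees, newdata) {
  votes <- vapply(trees, function(tr) {
    fedforest::tree_predict(tr, newdata)$vote
  }, integer(nrow(newdata)))
  votes <- matrix(votes, nrow = nrow(newdata))
  score <- rowMeans(votes)
  list(score = score, vote = as.integer(score > 0.5))
}

# random model-schema dataset for property tests
random_model_data <- function(n, seed, p_signal = 0.5) {
  withr::with_seed(seed, {
    d <- tibble::tibble(
      age = rnorm(n, 57, 9),
      sex01 = rbinom(n, 1, 0.8),
      waist = rnorm(n, 98, 11),
      cholesterol = rnorm(n, 228, 40),
      triglycerides = rlnorm(n, log(129), 0.45),
      hdl = rnorm(n, 51, 13),
      ldl = rnorm(n, 156, 35),
      hba1c = rnorm(n, 5.5, 0.5))
    d$label <- rbinom(n, 1, stats::plogis(p_signal * scale(d$age)[, 1]))
    if (length(unique(d$label)) == 1L) d$label[1] <- 1L - d$label[1]
    d
  })
}

# toy separable dataset: age <= 52.5 is class 0
toy_separable <- function() {
  tibble::tibble(
    age = c(40, 45, 50, 60, 65, 70),
    sex01 = c(1, 0, 1, 0, 1, 0),
    waist = 98, cholesterol = 228, triglycerides = 129,
    hdl = 51, ldl = 156, hba1c = 5.5,
    label = c(0, 0, 0, 1, 1, 1))
}

# small two-site cohort config that keeps unit tests fast
small_config <- function(seed = 1L, ...) {
  fedforest::cohort_config(n_total = 160, n_complete = 120,
                           site_counts = c(80, 40), seed = seed, ...)
}

small_sites <- function(seed = 1L, ...) {
  cohort <- fedforest::complete_case_filter(
    fedforest::generate_cohort(small_config(seed = seed, ...)),
    quiet = TRUE)
  fedforest::assemble_sites(cohort)
}

# internal feature-order constant, via the package namespace
MODEL_FEATURES <- function() fedforest:::MODEL_FEATURES
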