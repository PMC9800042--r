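---
title: "Federated random forests for CACS risk classification: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Federated random forests for CACS risk classification: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(fedforest)
library(dplyr)
```

## The problem

Coronary artery calcification (CAC) is scored from CT scans with an
Agatston-type score (CACS); a score of 5 or more is treated here as an
*elevated* finding worth flagging before a scan is even ordered. The
question the package addresses is operational rather than clinical: can two
medical institutions jointly train a random-forest classifier that predicts
elevated CACS from routine clinical measurements — **age, sex, waist
circumference, total cholesterol, triglycerides, HDL, LDL and HbA1c** —
*without ever pooling their patient records*, and does that federated model
pay a measurable performance price against the conventional centralized
model trained on the pooled data?

Because real multi-site patient data cannot be redistributed, the package
ships a calibrated synthetic cohort generator so the entire pipeline —
preprocessing, local training, tree merging, cross-site evaluation — is
exercised end to end on data with the same statistical skeleton as a real
two-site screening cohort.

## The federated mechanism

Random forests federate unusually cleanly: a forest is just a bag of
independently grown trees, so sites can train locally and share *trees*
instead of records.

1. **Allocation.** A global ensemble size $T$ (default 100) is apportioned
   across the $K$ sites proportionally to weights $w_k$ (by default the
   sites' sample counts) using largest-remainder rounding:
   each site gets $\lfloor T w_k / \sum w \rfloor$ trees and the leftover
   trees go to the largest fractional remainders (ties to the larger
   weight, then the lower site index; every site gets at least one tree).
   Under a 2:1 weighting of a 100-tree ensemble this gives 67/33; under
   the weights 477:202 it gives 70/30. Both conventions are supported —
   `allocate_trees()` takes arbitrary weights and `federated_train()`
   accepts a `weights` override — because "proportional to sample size"
   and a 2:1 convention genuinely disagree for a 477/202 split, and the
   package does not silently pick one: the default is true
   proportionality, the override reproduces the 2:1 convention.
2. **Local training.** Site $k$ grows its $T_k$ trees on its own data
   only. The training interface receives exactly one site's rows; the
   test suite additionally instruments the call boundary to assert that
   each per-site training call sees that site's dataset and nothing else.
3. **Merging.** `merge_forests()` concatenates the tree lists, preserving
   order and per-tree site provenance. Nothing is re-weighted or
   re-fitted; merging is associative, and the serialized forest (a JSON
   document of split nodes and leaf counts) is the only artifact that
   crosses site boundaries.
4. **Prediction.** The global forest scores a patient by the fraction of
   trees voting *elevated*; the forest votes elevated iff the score
   exceeds 1/2. The exact 0.5 tie goes to the normal class — the
   conservative direction for a rule-out screening aid — and the same
   convention applies inside a tree when a leaf holds equally many
   training samples of both classes. A `score = "fraction"` option uses
   the mean of leaf class fractions instead of hard votes.

## Tree induction

Trees are axis-aligned binary CART-style classifiers grown by gini
impurity minimization, implemented from scratch (with the split search in
compiled code, as every serious forest implementation does):

* Node impurity is $G = 1 - p_0^2 - p_1^2$; a split's quality is the
  child-size-weighted mean impurity, minimized over all candidate
  features and all midpoints between consecutive distinct sorted values.
* `mtry = 4` of the 8 features are drawn fresh, uniformly without
  replacement, at **every split**. The hyperparameter statement "4 random
  features per tree" is ambiguous between per-split and per-tree
  semantics; per-split is the standard random-forest meaning and is the
  default, while `feature_mode = "per_tree"` provides the random-subspace
  alternative.
* Unstated hyperparameters follow Breiman's canonical forest: bootstrap
  resampling on, unlimited depth, minimum leaf size 1. All are exposed in
  `forest_hyperparams()`.
* Determinism: ties in the split search are broken toward the lowest
  feature index and then the lowest threshold; every tree owns a private
  counter-based random stream derived from the forest seed via
  `derive_seed()`, so identical seeds give bit-identical serialized
  forests regardless of training order or platform (the compiled code
  uses its own Mersenne Twister rather than R's global RNG state).
* A split is only made if it strictly reduces impurity (tolerance
  $10^{-12}$); if the sampled candidate set admits no improving cut the
  node becomes a leaf. This means a tree can terminate early when an
  unlucky candidate draw contains only uninformative features — accepted
  behavior for mtry < p, and invisible at ensemble scale.

The split search is verified against an exhaustive brute-force oracle on
randomly generated instances (up to 50 samples, 8 features), and merged
forests are verified against an explicit majority vote over the union of
the tree lists.

## All-combinations cross-site cross-validation

Conventional k-fold CV assumes one pool of data. In the federated setting
each site makes ten even splits of *its own* data (random permutation,
then contiguous chunks whose sizes differ by at most one; unstratified by
default, since only evenness is required — a stratified option would be a
straightforward extension but is deliberately not the default).
Every cross-site pair of held-out splits $(i, j)$ then forms one
validation fold: site 1 trains on its nine remaining splits, site 2 on
its nine, the local forests are merged, and the merged model is scored on
the union of split $i$ and split $j$. Ten splits per site give exactly
$10 \times 10 = 100$ train/validate combinations; the whole procedure is
repeated ten times with fresh split plans, for 1000 recorded test runs.
Each repetition draws a fresh plan (rather than re-using one plan with
ten training restarts); this makes the repetitions genuine replicates of
the whole procedure, and both alternatives differ only in how much of the
variance comes from the split lottery.

The centralized reference model is evaluated on **exactly the same
validation unions**: for each $(i, j)$ it trains one forest on all pooled
rows except those two splits. How the centralized model was originally
validated is not specified anywhere; pairing it fold-for-fold with the
federated procedure is the design choice made here because it turns the
comparison into a paired one (identical validation rows per fold) and
gives both procedures the same $100 \times 10$ accounting. The
per-institution local baselines are each institution's own model under
ordinary 10-fold CV on its own data — the single-site degenerate case of
the same engine — at the full ensemble size; evaluating a local model on
the *other* site's data would measure transferability instead, which is a
different question.

Metrics are computed with *elevated* as the positive class: sensitivity
$TP/(TP+FN)$, specificity $TN/(TN+FP)$, accuracy, and a rank-based
(Mann–Whitney) ROC AUC with half credit for tied scores, verified against
explicit pair counting. A validation fold containing a single class
yields `NA` for the undefined metrics; these are excluded from means and
counted (`n_undefined_auc` in `glance()`), never coerced to zero.

## The synthetic cohort generator

`generate_cohort()` emulates the *preprocessed structure* of a two-site
screening cohort, by construction rather than by sampling:

* 1450 raw records, of which exactly 680 are complete; missingness is
  injected completely at random into exactly the other 770 rows (1–3
  clinical fields each), so the complete-case count is a certainty, not a
  binomial draw.
* The complete records split 477/203 between the institutions. The
  published per-site sizes 477 + 202 sum to 679, one short of the stated
  680 complete patients; the package defaults to 477/203 and documents
  the discrepancy rather than resolving it silently
  (`cohort_config(n_complete = 679, site_counts = c(477, 202))` uses the
  printed values verbatim).
* Labels first: exactly 340 of the complete records are *elevated*
  (CACS ≥ 5) and 340 *normal*, apportioned across sites by largest
  remainder. Features are then drawn conditional on the label from
  independent location families — normal for age, height, weight, waist,
  cholesterol, HDL, LDL and HbA1c; log-normal for the right-skewed
  triglycerides — whose *median* equals the calibration target for that
  feature and group (for a log-normal, median $= e^{\mu}$).
* The calibration targets are the group-wise medians of a real screening
  cohort: the elevated group is older (61 vs 54), has larger waist
  (101 vs 96), higher triglycerides (136 vs 122) and HbA1c (5.6 vs 5.4),
  and lower HDL (49 vs 53), cholesterol and LDL. Dispersions are not part
  of the calibration table, so the generator uses typical within-group
  clinical spreads (age SD 9 y, waist SD 11 cm, cholesterol SD
  40 mg/dL, HDL 13, LDL 35, HbA1c 0.5 points, triglycerides log-SD
  0.45), chosen once as realistic for an adult cardiac-screening
  population. With these choices age is by far the strongest single
  discriminator (standardized difference ≈ 0.78), which reproduces the
  qualitative expectation that locally trained trees split on age first.
* CACS itself is zero-inflated: normal-group patients have score 0 with
  probability 0.5 and otherwise a sub-threshold value; elevated-group
  scores are threshold plus a heavy-tailed log-normal excess.
* The two sites are statistically identical by default (`site_shift = 0`),
  matching the near-identical per-site medians of the calibration table;
  a site shift is available to study heterogeneous federations.
* Height, weight (and hence BMI) are generated so the cohort is a
  complete clinical record, but they are **not** model features; BMI is
  derivable and never stored, so it can never disagree with
  height/weight.

What the generator deliberately does *not* model: correlations between
features within a label group (waist, triglycerides and HbA1c are
independent draws here; in patients they co-vary), site-level case-mix
differences, measurement error, informative missingness, or longitudinal
structure. Passing tests on this cohort therefore demonstrate that the
*mechanism* — allocation, merging, paired CV, metric accounting — is
correct and that the federated/centralized gap is small when sites are
homogeneous; they do not certify clinical performance on real data, where
feature correlations and site heterogeneity can move all metrics.

```{r medians, fig.width = 7, fig.height = 4}
cohort <- generate_cohort(cohort_config(seed = 42))
complete <- complete_case_filter(cohort)
plot_cohort_medians(complete)
```

## Numerical and scale choices

* Split thresholds sit at midpoints of consecutive distinct values;
  traversal uses `value <= threshold` goes left, so a value exactly at a
  threshold routes left, and serialized thresholds are written at full
  precision so a JSON round trip reproduces predictions bit-exactly.
* Imputation (the `impute = "mean"/"median"` alternative to complete-case
  filtering) computes its statistics per institution: pooling
  column means across sites would itself leak data in a federated
  setting. Complete-case filtering is the default pipeline.
* Sex is encoded M = 1, F = 0 at feature-assembly time; any consistent
  encoding is equivalent for trees, one is fixed for serialization
  stability.
* The test suite runs its full-scale cross-validation at 20 trees per
  ensemble: fold combinatorics and the paired federated-vs-centralized
  comparison are invariant to ensemble size, and 20 trees keeps two
  1000-fold runs to a few minutes on a single core. The worked
  example below and the shipped experiment default stay at 100 trees.

## A compact worked example

A reduced experiment (3 splits, 30 trees, 1 repetition) shows the shape
of the full run:

```{r experiment}
res <- run_experiment(config = cohort_config(seed = 42),
                      n_splits = 3, total_trees = 30,
                      n_repetitions = 1, seed = 7)
res$summary |> mutate(across(where(is.numeric), ~ round(.x, 3)))
```

```{r report-plot, fig.width = 7, fig.height = 5}
autoplot(res$report)
```

The full-scale configuration (10 splits, 100 trees, 10 repetitions —
1000 folds per model) is what `run_experiment()` runs by default.

## Known limitations

* Independence of features within a label group is the generator's
  strongest simplification; real risk factors are correlated, which
  typically makes the *joint* signal weaker than the sum of marginal
  signals suggests.
* The federated mechanism shares fully grown trees; split thresholds on
  small leaves can in principle leak information about individual
  records. Differential privacy and secure aggregation are out of scope
  here.
* Two-class, axis-aligned classification only; no regression forests,
  pruning, or feature importance.
* The all-combinations scheme costs $n_{\text{splits}}^K$ model fits for
  $K$ sites and is meant for small federations; it generalizes to
  arbitrary $K$ (the Cartesian product of per-site splits) but the cost
  grows geometrically.
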