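#include <Rcpp.h>
#include <random>
#include <vector>
#include <algorithm>
#include <cstdint>

using namespace Rcpp;

// Deterministic bounded draw. std::uniform_int_distribution is
// implementation-defined; raw modulo on mt19937 output is portable and the
// slight bias is irrelevant at these ranges (p <= 8, n <= a few thousand).
static inline uint32_t rand_below(std::mt19937 &gen, uint32_t n) {
  return gen() % n;
}

static inline double gini_from_counts(double c0, double c1) {
  double n = c0 + c1;
  double p0 = c0 / n, p1 = c1 / n;
  return 1.0 - p0 * p0 - p1 * p1;
}

struct SplitResult {
  bool found;
  int feature;      // 0-based
  double threshold; // go left iff x <= threshold
  double impurity;  // child-count-weighted mean gini
};

// Exhaustive scan over candidate features (ascending) and midpoint
// thresholds (ascending). Ties broken toward lowest feature index, then
// lowest threshold, via strict improvement with a small tolerance.
static SplitResult best_split_impl(const NumericMatrix &X,
                                   const IntegerVector &y,
                                   const std::vector<int> &idx,
                                   const std::vector<int> &candidates,
                                   int min_leaf) {
  const double EPS = 1e-12;
  SplitResult best{false, -1, 0.0, R_PosInf};
  size_t n = idx.size();
  std::vector<int> ord(n);
  std::vector<double> xv(n);

  for (int f : candidates) {
    for (size_t i = 0; i < n; ++i) xv[i] = X(idx[i], f);
    for (size_t i = 0; i < n; ++i) ord[i] = (int)i;
    std::sort(ord.begin(), ord.end(),
              [&](int a, int b) { return xv[a] < xv[b]; });

    double tot1 = 0;
    for (size_t i = 0; i < n; ++i) tot1 += y[idx[i]];
    double tot0 = (double)n - tot1;

    double l0 = 0, l1 = 0;
    for (size_t k = 1; k < n; ++k) {
      int yi = y[idx[ord[k - 1]]];
      if (yi == 1) l1 += 1; else l0 += 1;
      double xlo = xv[ord[k - 1]], xhi = xv[ord[k]];
      if (xhi <= xlo) continue; // not a boundary between distinct values
      double nl = (double)k, nr = (double)(n - k);
      if (nl < min_leaf || nr < min_leaf) continue;
      double gl = gini_from_counts(l0, l1);
      double gr = gini_from_counts(tot0 - l0, tot1 - l1);
      double g = (nl * gl + nr * gr) / (double)n;
      if (g < best.impurity - EPS) {
        best.found = true;
        best.feature = f;
        best.threshold = 0.5 * (xlo + xhi);
        best.impurity = g;
      }
    }
  }
  return best;
}

// [[Rcpp::export(name = ".best_split_cpp")]]
List best_split_cpp(NumericMatrix X, IntegerVector y,
                    IntegerVector candidates, int min_leaf) {
  std::vector<int> idx(X.nrow());
  for (int i = 0; i < X.nrow(); ++i) idx[i] = i;
  std::vector<int> cand(candidates.begin(), candidates.end());
  std::sort(cand.begin(), cand.end());

  double c1 = 0;
  for (int i = 0; i < X.nrow(); ++i) c1 += y[i];
  double c0 = X.nrow() - c1;
  SplitResult s = best_split_impl(X, y, idx, cand, min_leaf);
  // only report a split that reduces impurity below the parent's
  bool improves = s.found &&
    s.impurity < gini_from_counts(c0, c1) - 1e-12;
  return List::create(_["found"] = improves,
                      _["feature"] = s.feature,
                      _["threshold"] = s.threshold,
                      _["impurity"] = s.impurity);
}

struct TreeBuf {
  std::vector<int> feature;
  std::vector<double> threshold;
  std::vector<int> left, right, n0, n1;
  int add_node() {
    feature.push_back(-1);
    threshold.push_back(NA_REAL);
    left.push_back(-1);
    right.push_back(-1);
    n0.push_back(0);
    n1.push_back(0);
    return (int)feature.size() - 1;
  }
};

static void draw_candidates(std::mt19937 &gen, int p, int mtry,
                            std::vector<int> &out) {
  std::vector<int> pool(p);
  for (int i = 0; i < p; ++i) pool[i] = i;
  out.clear();
  for (int i = 0; i < mtry; ++i) {
    int j = i + (int)rand_below(gen, (uint32_t)(p - i));
    std::swap(pool[i], pool[j]);
    out.push_back(pool[i]);
  }
  std::sort(out.begin(), out.end());
}

static int grow_node(const NumericMatrix &X, const IntegerVector &y,
                     std::vector<int> &idx, int depth, int mtry,
                     int min_leaf, int max_depth, bool per_tree_features,
                     const std::vector<int> &fixed_candidates,
                     std::mt19937 &gen, TreeBuf &buf) {
  int node = buf.add_node();
  int c1 = 0;
  for (int i : idx) c1 += y[i];
  int c0 = (int)idx.size() - c1;
  buf.n0[node] = c0;
  buf.n1[node] = c1;

  bool stop = (c0 == 0 || c1 == 0) || ((int)idx.size() < 2 * min_leaf) ||
              ((int)idx.size() < 2) ||
              (max_depth >= 0 && depth >= max_depth);
  if (!stop) {
    std::vector<int> cand;
    if (per_tree_features) {
      cand = fixed_candidates;
    } else {
      int p = X.ncol();
      draw_candidates(gen, p, std::min(mtry, p), cand);
    }
    SplitResult s = best_split_impl(X, y, idx, cand, min_leaf);
    double parent_g = gini_from_counts((double)c0, (double)c1);
    if (s.found && s.impurity < parent_g - 1e-12) {
      std::vector<int> lidx, ridx;
      lidx.reserve(idx.size());
      ridx.reserve(idx.size());
      for (int i : idx) {
        if (X(i, s.feature) <= s.threshold) lidx.push_back(i);
        else ridx.push_back(i);
      }
      buf.feature[node] = s.feature;
      buf.threshold[node] = s.threshold;
      { std::vector<int>().swap(idx); } // free before recursing
      int lchild = grow_node(X, y, lidx, depth + 1, mtry, min_leaf,
                             max_depth, per_tree_features, fixed_candidates,
                             gen, buf);
      int rchild = grow_node(X, y, ridx, depth + 1, mtry, min_leaf,
                             max_depth, per_tree_features, fixed_candidates,
                             gen, buf);
      buf.left[node] = lchild;
      buf.right[node] = rchild;
    }
  }
  return node;
}

// [[Rcpp::export(name = ".grow_tree_cpp")]]
List grow_tree_cpp(NumericMatrix X, IntegerVector y, int mtry, int min_leaf,
                   int max_depth, bool bootstrap, bool per_tree_features,
                   double seed) {
  int n = X.nrow(), p = X.ncol();
  if (n < 1) stop("empty dataset");
  std::mt19937 gen((uint32_t)seed);

  std::vector<int> idx(n);
  if (bootstrap) {
    for (int i = 0; i < n; ++i) idx[i] = (int)rand_below(gen, (uint32_t)n);
  } else {
    for (int i = 0; i < n; ++i) idx[i] = i;
  }

  std::vector<int> fixed;
  if (per_tree_features) draw_candidates(gen, p, std::min(mtry, p), fixed);

  TreeBuf buf;
  grow_node(X, y, idx, 0, mtry, min_leaf, max_depth, per_tree_features,
            fixed, gen, buf);

  return List::create(
      _["feature"] = IntegerVector(buf.feature.begin(), buf.feature.end()),
      _["threshold"] = NumericVector(buf.threshold.begin(),
                                     buf.threshold.end()),
      _["left"] = IntegerVector(buf.left.begin(), buf.left.end()),
      _["right"] = IntegerVector(buf.right.begin(), buf.right.end()),
      _["n0"] = IntegerVector(buf.n0.begin(), buf.n0.end()),
      _["n1"] = IntegerVector(buf.n1.begin(), buf.n1.end()));
}

// [[Rcpp::export(name = ".predict_tree_cpp")]]
List predict_tree_cpp(IntegerVector feature, NumericVector threshold,
                      IntegerVector left, IntegerVector right,
                      IntegerVector n0, IntegerVector n1, NumericMatrix X) {
  int n = X.nrow();
  IntegerVector vote(n);
  NumericVector frac(n);
  for (int i = 0; i < n; ++i) {
    int node = 0;
    while (feature[node] >= 0) {
      int f = feature[node];
      if (f >= X.ncol()) stop("corrupt model: feature index out of range");
      node = (X(i, f) <= threshold[node]) ? left[node] : right[node];
      if (node < 0) stop("corrupt model: dangling child pointer");
    }
    double tot = (double)n0[node] + (double)n1[node];
    frac[i] = n1[node] / tot;
    vote[i] = (n1[node] > n0[node]) ? 1 : 0; // tie -> normal (class 0)
  }
  return List::create(_["vote"] = vote, _["frac"] = frac);
}
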