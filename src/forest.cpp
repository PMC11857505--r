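// Bagged decision-tree ensemble for small two-class cohorts.
//
// Each tree is grown on a bootstrap resample using a random subspace of
// `mtry` features chosen once per tree, with gini or entropy impurity
// (the log-loss criterion is the entropy impurity), bounded depth, and
// minimum-samples-to-split / minimum-samples-per-leaf constraints. All
// randomness comes from a std::mt19937 seeded explicitly, so results are
// reproducible across platforms independently of R's RNG state.
//
// Trees are returned as flat node tables, which also back the exact
// Shapley attribution: a tree depends only on its own split features, so
// per-tree Shapley values can be computed by enumerating subsets of those
// features with path-dependent conditional expectations, and summed across
// trees (linearity); features a tree never splits on are dummies with
// attribution zero.

#include <Rcpp.h>
#include <random>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

struct TreeNode {
  int feature;      // -1 for leaf
  double threshold; // go left when x <= threshold
  int left, right;
  double n;         // bootstrap sample count reaching the node
  double p1;        // class-1 (RA) fraction at the node
};

static double impurity(double n0, double n1, int crit) {
  double n = n0 + n1;
  if (n <= 0) return 0.0;
  double p0 = n0 / n, p1 = n1 / n;
  if (crit == 0) { // gini
    return 1.0 - p0 * p0 - p1 * p1;
  }
  double h = 0.0; // entropy (== log_loss impurity)
  if (p0 > 0) h -= p0 * std::log2(p0);
  if (p1 > 0) h -= p1 * std::log2(p1);
  return h;
}

// Recursively grow a tree over the bootstrap indices `idx`.
static int grow(const NumericMatrix& X, const IntegerVector& y,
                std::vector<int>& idx, const std::vector<int>& feats,
                int depth, int max_depth, int min_split, int min_leaf,
                int crit, std::vector<TreeNode>& nodes) {
  int n = (int)idx.size();
  double n1 = 0;
  for (int i : idx) n1 += y[i];
  double n0 = n - n1;

  TreeNode node;
  node.feature = -1;
  node.threshold = 0.0;
  node.left = node.right = -1;
  node.n = n;
  node.p1 = n > 0 ? n1 / n : 0.5;

  bool can_split = depth < max_depth && n >= min_split && n0 > 0 && n1 > 0;
  int best_f = -1;
  double best_thr = 0.0, best_imp = impurity(n0, n1, crit);
  const double eps = 1e-12;

  if (can_split) {
    std::vector<std::pair<double,int>> vals(n);
    for (int f : feats) {
      for (int k = 0; k < n; ++k)
        vals[k] = std::make_pair(X(idx[k], f), y[idx[k]]);
      std::sort(vals.begin(), vals.end());
      double l1 = 0, l0 = 0;
      for (int k = 0; k < n - 1; ++k) {
        if (vals[k].second == 1) l1 += 1; else l0 += 1;
        if (vals[k].first == vals[k + 1].first) continue; // no boundary here
        double nl = l0 + l1, nr = n - nl;
        if (nl < min_leaf || nr < min_leaf) continue;
        double imp = (nl * impurity(l0, l1, crit) +
                      nr * impurity(n0 - l0, n1 - l1, crit)) / n;
        if (imp < best_imp - eps) { // strict improvement; first feature wins ties
          best_imp = imp;
          best_f = f;
          best_thr = (vals[k].first + vals[k + 1].first) / 2.0;
        }
      }
    }
  }

  int self = (int)nodes.size();
  nodes.push_back(node);
  if (best_f >= 0) {
    std::vector<int> li, ri;
    for (int i : idx) {
      if (X(i, best_f) <= best_thr) li.push_back(i); else ri.push_back(i);
    }
    nodes[self].feature = best_f;
    nodes[self].threshold = best_thr;
    int l = grow(X, y, li, feats, depth + 1, max_depth, min_split, min_leaf,
                 crit, nodes);
    int r = grow(X, y, ri, feats, depth + 1, max_depth, min_split, min_leaf,
                 crit, nodes);
    nodes[self].left = l;
    nodes[self].right = r;
  }
  return self;
}

// Fit the ensemble. crit: 0 = gini, 1 = entropy/log_loss.
// [[Rcpp::export(name = ".cpp_forest_fit")]]
List cpp_forest_fit(NumericMatrix X, IntegerVector y, int n_trees, int mtry,
                    int max_depth, int min_split, int min_leaf, int crit,
                    int seed) {
  int n = X.nrow(), p = X.ncol();
  if (mtry < 1) mtry = 1;
  if (mtry > p) mtry = p;
  std::mt19937 rng((unsigned)seed);
  std::uniform_int_distribution<int> pick(0, n - 1);
  List trees(n_trees);
  for (int t = 0; t < n_trees; ++t) {
    // bootstrap resample
    std::vector<int> idx(n);
    for (int i = 0; i < n; ++i) idx[i] = pick(rng);
    // random subspace: mtry distinct features for this tree
    std::vector<int> perm(p);
    for (int i = 0; i < p; ++i) perm[i] = i;
    for (int i = p - 1; i > 0; --i) {
      std::uniform_int_distribution<int> d(0, i);
      std::swap(perm[i], perm[d(rng)]);
    }
    // keep shuffle order: equal-gain ties resolve to the earliest feature
    // in this order, which varies across trees
    std::vector<int> feats(perm.begin(), perm.begin() + mtry);

    std::vector<TreeNode> nodes;
    grow(X, y, idx, feats, 0, max_depth, min_split, min_leaf, crit, nodes);

    int m = (int)nodes.size();
    IntegerVector feature(m), left(m), right(m);
    NumericVector threshold(m), nn(m), p1(m);
    for (int i = 0; i < m; ++i) {
      feature[i] = nodes[i].feature;
      threshold[i] = nodes[i].threshold;
      left[i] = nodes[i].left;
      right[i] = nodes[i].right;
      nn[i] = nodes[i].n;
      p1[i] = nodes[i].p1;
    }
    trees[t] = List::create(_["feature"] = feature,
                            _["threshold"] = threshold,
                            _["left"] = left, _["right"] = right,
                            _["n"] = nn, _["p1"] = p1,
                            _["feats"] = wrap(feats));
  }
  return trees;
}

static double tree_prob(const IntegerVector& feature,
                        const NumericVector& threshold,
                        const IntegerVector& left, const IntegerVector& right,
                        const NumericVector& p1, const NumericMatrix& X,
                        int row) {
  int node = 0;
  while (feature[node] >= 0) {
    node = (X(row, feature[node]) <= threshold[node]) ? left[node]
                                                      : right[node];
  }
  return p1[node];
}

// Mean class-1 probability over trees for each row of X.
// [[Rcpp::export(name = ".cpp_forest_predict")]]
NumericVector cpp_forest_predict(List trees, NumericMatrix X) {
  int n = X.nrow(), T = trees.size();
  NumericVector out(n);
  for (int t = 0; t < T; ++t) {
    List tr = trees[t];
    IntegerVector feature = tr["feature"], left = tr["left"],
                  right = tr["right"];
    NumericVector threshold = tr["threshold"], p1 = tr["p1"];
    for (int i = 0; i < n; ++i)
      out[i] += tree_prob(feature, threshold, left, right, p1, X, i);
  }
  for (int i = 0; i < n; ++i) out[i] /= T;
  return out;
}

// Path-dependent conditional expectation of a tree's class-1 probability
// when only the features in `inS` are known to take x's values; absent
// features are marginalized by the bootstrap node proportions.
static double tree_expect(const IntegerVector& feature,
                          const NumericVector& threshold,
                          const IntegerVector& left, const IntegerVector& right,
                          const NumericVector& nn, const NumericVector& p1,
                          const NumericMatrix& X, int row,
                          const std::vector<bool>& inS, int node) {
  int f = feature[node];
  if (f < 0) return p1[node];
  if (inS[f]) {
    int nxt = (X(row, f) <= threshold[node]) ? left[node] : right[node];
    return tree_expect(feature, threshold, left, right, nn, p1, X, row, inS,
                       nxt);
  }
  double nl = nn[left[node]], nr = nn[right[node]], ntot = nl + nr;
  if (ntot <= 0) return p1[node];
  return (nl * tree_expect(feature, threshold, left, right, nn, p1, X, row,
                           inS, left[node]) +
          nr * tree_expect(feature, threshold, left, right, nn, p1, X, row,
                           inS, right[node])) / ntot;
}

// Exact Shapley values of the ensemble's class-1 probability for each row
// of X, by per-tree subset enumeration over the tree's own split features.
// Returns list(values = n x p matrix, base_value = scalar).
// [[Rcpp::export(name = ".cpp_forest_shapley")]]
List cpp_forest_shapley(List trees, NumericMatrix X) {
  int n = X.nrow(), p = X.ncol(), T = trees.size();
  NumericMatrix phi(n, p);
  double base = 0.0;

  // factorial table for Shapley weights (|used| <= ~25)
  std::vector<double> fact(64);
  fact[0] = 1.0;
  for (int i = 1; i < 64; ++i) fact[i] = fact[i - 1] * i;

  for (int t = 0; t < T; ++t) {
    List tr = trees[t];
    IntegerVector feature = tr["feature"], left = tr["left"],
                  right = tr["right"];
    NumericVector threshold = tr["threshold"], nn = tr["n"], p1 = tr["p1"];

    // distinct features actually used in splits
    std::vector<int> used;
    for (int i = 0; i < feature.size(); ++i) {
      if (feature[i] >= 0 &&
          std::find(used.begin(), used.end(), feature[i]) == used.end())
        used.push_back(feature[i]);
    }
    int m = (int)used.size();
    if (m > 25) stop("tree uses too many features for exact enumeration");
    int nsub = 1 << m;

    if (m == 0) { base += p1[0]; continue; }

    std::vector<double> vs(nsub);
    std::vector<bool> inS(p, false);
    for (int row = 0; row < n; ++row) {
      for (int s = 0; s < nsub; ++s) {
        std::fill(inS.begin(), inS.end(), false);
        for (int b = 0; b < m; ++b)
          if (s & (1 << b)) inS[used[b]] = true;
        vs[s] = tree_expect(feature, threshold, left, right, nn, p1, X, row,
                            inS, 0);
      }
      if (row == 0) base += vs[0];
      for (int b = 0; b < m; ++b) {
        double ph = 0.0;
        for (int s = 0; s < nsub; ++s) {
          if (s & (1 << b)) continue;
          int sz = 0;
          for (int c = 0; c < m; ++c) if (s & (1 << c)) ++sz;
          double w = fact[sz] * fact[m - sz - 1] / fact[m];
          ph += w * (vs[s | (1 << b)] - vs[s]);
        }
        phi(row, used[b]) += ph;
      }
    }
  }
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < p; ++j) phi(i, j) /= T;
  return List::create(_["values"] = phi, _["base_value"] = base / T);
}
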