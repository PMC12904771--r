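// Minimal CART engine backing the random forest and gradient-boosting
// classifiers: axis-aligned binary trees with exact split search over
// sorted feature values, mtry feature subsampling per node, gini/entropy
// impurity for classification and variance reduction for regression.

#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <random>
#include <cmath>
using namespace Rcpp;

struct Node {
  int feature = -1;      // -1 = leaf
  double threshold = 0;  // x <= threshold goes left
  int left = -1, right = -1;
  double value = 0;      // class-1 probability or mean residual
};

struct Grower {
  const NumericMatrix& X;
  const NumericVector& y;      // 0/1 labels or residuals
  const NumericVector& w;      // per-row weights (GB Newton denominators use R side)
  bool regression;
  int criterion;               // 0 = gini, 1 = entropy (classification only)
  int mtry, max_depth, min_split;
  std::mt19937 rng;
  std::vector<Node> nodes;

  Grower(const NumericMatrix& X_, const NumericVector& y_,
         const NumericVector& w_, bool reg, int crit, int mtry_,
         int max_depth_, int min_split_, unsigned seed)
    : X(X_), y(y_), w(w_), regression(reg), criterion(crit), mtry(mtry_),
      max_depth(max_depth_), min_split(min_split_), rng(seed) {}

  double impurity(double sw, double s1) const {
    if (sw <= 0) return 0.0;
    if (regression) return 0.0;  // unused
    double p = s1 / sw;
    if (criterion == 0) return 2.0 * p * (1.0 - p);
    double h = 0.0;
    if (p > 0) h -= p * std::log(p);
    if (p < 1) h -= (1.0 - p) * std::log(1.0 - p);
    return h;
  }

  int grow(std::vector<int>& idx, int depth) {
    int id = (int)nodes.size();
    nodes.push_back(Node());
    double sw = 0, sy = 0, syy = 0;
    for (int i : idx) { sw += w[i]; sy += w[i] * y[i]; syy += w[i] * y[i] * y[i]; }
    nodes[id].value = sw > 0 ? sy / sw : 0.0;

    bool pure = regression ? (syy - sy * sy / std::max(sw, 1e-300) < 1e-12)
                           : (sy < 1e-12 || sw - sy < 1e-12);
    if (depth >= max_depth || (int)idx.size() < min_split || pure) return id;

    // candidate features: mtry without replacement
    int p = X.ncol();
    std::vector<int> feats(p);
    for (int k = 0; k < p; ++k) feats[k] = k;
    std::shuffle(feats.begin(), feats.end(), rng);
    int ntry = std::min(mtry, p);

    double best_gain = 1e-12;
    int best_f = -1; double best_thr = 0;
    double parent = regression ? (syy - sy * sy / sw) : sw * impurity(sw, sy);

    std::vector<std::pair<double, int>> v;
    v.reserve(idx.size());
    for (int t = 0; t < ntry; ++t) {
      int f = feats[t];
      v.clear();
      for (int i : idx) v.push_back({X(i, f), i});
      std::sort(v.begin(), v.end());
      double lw = 0, ly = 0, lyy = 0;
      for (size_t k = 0; k + 1 < v.size(); ++k) {
        int i = v[k].second;
        lw += w[i]; ly += w[i] * y[i]; lyy += w[i] * y[i] * y[i];
        if (v[k + 1].first <= v[k].first) continue;  // not a distinct cut
        double rw = sw - lw, ry = sy - ly, ryy = syy - lyy;
        if (lw <= 0 || rw <= 0) continue;
        double child = regression
          ? (lyy - ly * ly / lw) + (ryy - ry * ry / rw)
          : lw * impurity(lw, ly) + rw * impurity(rw, ry);
        double gain = parent - child;
        if (gain > best_gain) {
          best_gain = gain; best_f = f;
          best_thr = 0.5 * (v[k].first + v[k + 1].first);
        }
      }
    }
    if (best_f < 0) return id;

    std::vector<int> li, ri;
    for (int i : idx) (X(i, best_f) <= best_thr ? li : ri).push_back(i);
    if (li.empty() || ri.empty()) return id;
    nodes[id].feature = best_f;
    nodes[id].threshold = best_thr;
    nodes[id].left = grow(li, depth + 1);
    nodes[id].right = grow(ri, depth + 1);
    return id;
  }
};

// [[Rcpp::export(name = ".cpp_grow_tree")]]
List cpp_grow_tree(NumericMatrix X, NumericVector y, NumericVector w,
                   IntegerVector idx, bool regression, int criterion,
                   int mtry, int max_depth, int min_split, int seed) {
  Grower g(X, y, w, regression, criterion, mtry, max_depth, min_split,
           (unsigned)seed);
  std::vector<int> rows(idx.begin(), idx.end());  // 0-based sample rows
  g.grow(rows, 0);
  int n = (int)g.nodes.size();
  IntegerVector feature(n), left(n), right(n);
  NumericVector threshold(n), value(n);
  for (int k = 0; k < n; ++k) {
    feature[k] = g.nodes[k].feature;
    threshold[k] = g.nodes[k].threshold;
    left[k] = g.nodes[k].left;
    right[k] = g.nodes[k].right;
    value[k] = g.nodes[k].value;
  }
  return List::create(_["feature"] = feature, _["threshold"] = threshold,
                      _["left"] = left, _["right"] = right,
                      _["value"] = value);
}

// Returns for each row of X the node index (0-based) of the leaf it lands in.
// [[Rcpp::export(name = ".cpp_tree_apply")]]
IntegerVector cpp_tree_apply(List tree, NumericMatrix X) {
  IntegerVector feature = tree["feature"], left = tree["left"],
                right = tree["right"];
  NumericVector threshold = tree["threshold"];
  int n = X.nrow();
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) {
    int node = 0;
    while (feature[node] >= 0)
      node = X(i, feature[node]) <= threshold[node] ? left[node] : right[node];
    out[i] = node;
  }
  return out;
}
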