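#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// CART backend shared by the random forest and the gradient-boosted model.
// Trees are returned as flat node tables so R-side code can compute
// node-improvement importance, extract pure trees and print rule lists
// without touching C++ again.
//
// Node encoding (0-based indices, -1 for "none"):
//   feature   split feature, -1 for leaves
//   threshold split point (go left if x <= threshold)
//   left/right child node ids
//   n         training samples reaching the node
//   value     class-1 proportion (classification) or mean response (regression)
//   impurity  Gini (classification) or variance (regression) at the node
//   improvement  impurity(parent) - nL/n * impurity(L) - nR/n * impurity(R)

namespace {

struct NodeJob {
  int id;
  std::vector<int> rows;
  int depth;
};

inline double gini(double n1, double n) {
  if (n <= 0.0) return 0.0;
  double p = n1 / n;
  return 2.0 * p * (1.0 - p);
}

// Fisher-Yates draw of m items from 0..(p-1) using R's RNG so results are
// reproducible under set.seed().
std::vector<int> sample_features(int p, int m) {
  std::vector<int> pool(p);
  for (int i = 0; i < p; ++i) pool[i] = i;
  for (int i = 0; i < m; ++i) {
    int j = i + (int)(unif_rand() * (p - i));
    if (j >= p) j = p - 1;
    std::swap(pool[i], pool[j]);
  }
  pool.resize(m);
  return pool;
}

} // namespace

// [[Rcpp::export(name = ".cpp_grow_tree")]]
List cpp_grow_tree(NumericMatrix X, NumericVector y, IntegerVector rows0,
                   bool regression, int mtry, int max_depth, int min_node,
                   double min_improve) {
  const int p = X.ncol();
  if (mtry < 1) mtry = 1;
  if (mtry > p) mtry = p;

  std::vector<int> feature, left, right, nn;
  std::vector<double> threshold, value, impurity, improvement;

  std::vector<NodeJob> stack;
  {
    NodeJob root;
    root.id = 0;
    root.rows.assign(rows0.begin(), rows0.end());
    root.depth = 0;
    stack.push_back(root);
    feature.push_back(-1); left.push_back(-1); right.push_back(-1);
    nn.push_back((int)root.rows.size());
    threshold.push_back(NA_REAL); value.push_back(0.0);
    impurity.push_back(0.0); improvement.push_back(0.0);
  }

  std::vector<double> xv;
  std::vector<int> ord;

  while (!stack.empty()) {
    NodeJob job = stack.back();
    stack.pop_back();
    const std::vector<int> &rows = job.rows;
    const int n = (int)rows.size();

    double sum = 0.0, sum2 = 0.0;
    for (int r : rows) { double yi = y[r]; sum += yi; sum2 += yi * yi; }
    double node_value = n > 0 ? sum / n : 0.0;
    double node_imp;
    if (regression) {
      node_imp = n > 0 ? sum2 / n - node_value * node_value : 0.0;
      if (node_imp < 0) node_imp = 0.0;
    } else {
      node_imp = gini(sum, (double)n);
    }
    value[job.id] = node_value;
    impurity[job.id] = node_imp;
    nn[job.id] = n;

    bool splittable = n >= min_node * 2 && node_imp > 1e-12 &&
                      (max_depth < 0 || job.depth < max_depth);
    if (!splittable) continue;

    std::vector<int> feats = sample_features(p, mtry);
    int best_f = -1, best_cut = -1;
    double best_impr = min_improve, best_thr = NA_REAL;
    std::vector<int> best_ord;

    for (int f : feats) {
      xv.resize(n);
      ord.resize(n);
      for (int i = 0; i < n; ++i) { xv[i] = X(rows[i], f); ord[i] = i; }
      std::sort(ord.begin(), ord.end(),
                [&](int a, int b) { return xv[a] < xv[b]; });
      double csum = 0.0, csum2 = 0.0;
      for (int i = 0; i < n - 1; ++i) {
        double yi = y[rows[ord[i]]];
        csum += yi; csum2 += yi * yi;
        if (xv[ord[i]] == xv[ord[i + 1]]) continue;
        int nl = i + 1, nr = n - nl;
        if (nl < min_node || nr < min_node) continue;
        double impL, impR;
        if (regression) {
          double mL = csum / nl, mR = (sum - csum) / nr;
          impL = csum2 / nl - mL * mL;
          impR = (sum2 - csum2) / nr - mR * mR;
          if (impL < 0) impL = 0.0;
          if (impR < 0) impR = 0.0;
        } else {
          impL = gini(csum, (double)nl);
          impR = gini(sum - csum, (double)nr);
        }
        double impr = node_imp - ((double)nl / n) * impL - ((double)nr / n) * impR;
        if (impr > best_impr) {
          best_impr = impr;
          best_f = f;
          best_cut = i;
          best_thr = 0.5 * (xv[ord[i]] + xv[ord[i + 1]]);
          best_ord = ord;
        }
      }
    }

    if (best_f < 0) continue;

    feature[job.id] = best_f;
    threshold[job.id] = best_thr;
    improvement[job.id] = best_impr;

    NodeJob lj, rj;
    lj.depth = rj.depth = job.depth + 1;
    for (int i = 0; i <= best_cut; ++i) lj.rows.push_back(rows[best_ord[i]]);
    for (int i = best_cut + 1; i < n; ++i) rj.rows.push_back(rows[best_ord[i]]);

    lj.id = (int)feature.size();
    feature.push_back(-1); left.push_back(-1); right.push_back(-1);
    nn.push_back((int)lj.rows.size());
    threshold.push_back(NA_REAL); value.push_back(0.0);
    impurity.push_back(0.0); improvement.push_back(0.0);

    rj.id = (int)feature.size();
    feature.push_back(-1); left.push_back(-1); right.push_back(-1);
    nn.push_back((int)rj.rows.size());
    threshold.push_back(NA_REAL); value.push_back(0.0);
    impurity.push_back(0.0); improvement.push_back(0.0);

    left[job.id] = lj.id;
    right[job.id] = rj.id;
    stack.push_back(rj);
    stack.push_back(lj);
  }

  return List::create(
      _["feature"] = wrap(feature), _["threshold"] = wrap(threshold),
      _["left"] = wrap(left), _["right"] = wrap(right), _["n"] = wrap(nn),
      _["value"] = wrap(value), _["impurity"] = wrap(impurity),
      _["improvement"] = wrap(improvement));
}

// [[Rcpp::export(name = ".cpp_tree_leaf")]]
IntegerVector cpp_tree_leaf(List tree, NumericMatrix X) {
  IntegerVector feature = tree["feature"];
  NumericVector threshold = tree["threshold"];
  IntegerVector left = tree["left"], right = tree["right"];
  const int n = X.nrow();
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) {
    int node = 0;
    while (feature[node] >= 0) {
      node = X(i, feature[node]) <= threshold[node] ? left[node] : right[node];
    }
    out[i] = node; // 0-based leaf node id
  }
  return out;
}

// [[Rcpp::export(name = ".cpp_tree_predict")]]
NumericVector cpp_tree_predict(List tree, NumericMatrix X) {
  NumericVector value = tree["value"];
  IntegerVector leaf = cpp_tree_leaf(tree, X);
  const int n = X.nrow();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = value[leaf[i]];
  return out;
}
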