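// Minimal exact-greedy gradient-boosted regression trees (squared error),
// following the usual second-order boosting formulation: per node with
// gradient sum G and hessian sum H (H = n for squared error), leaf weight
// -G/(H + lambda) and split gain
//   1/2 [ GL^2/(HL+la) + GR^2/(HR+la) - G^2/(H+la) ].
// Deterministic: no row/column subsampling, midpoint thresholds, first best
// split wins ties.

#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

struct Node {
  int feature;      // -1 for leaf
  double threshold; // go left if x < threshold
  int left, right;  // child indices
  double value;     // leaf value
};

static void grow(std::vector<Node> &nodes, int node_id,
                 const NumericMatrix &X, const std::vector<double> &grad,
                 std::vector<int> &idx, int lo, int hi,
                 int depth, int max_depth, double lambda,
                 int min_child) {
  const int n = hi - lo;
  double G = 0.0;
  for (int k = lo; k < hi; ++k) G += grad[idx[k]];
  double H = (double)n;

  double base = G * G / (H + lambda);
  double best_gain = 0.0, best_thr = 0.0;
  int best_feat = -1;

  if (depth < max_depth && n >= 2 * min_child) {
    const int p = X.ncol();
    std::vector<std::pair<double, double>> v(n);  // (x, grad)
    for (int f = 0; f < p; ++f) {
      for (int k = 0; k < n; ++k) {
        int i = idx[lo + k];
        v[k] = std::make_pair(X(i, f), grad[i]);
      }
      std::sort(v.begin(), v.end());
      double GL = 0.0;
      for (int k = 0; k < n - 1; ++k) {
        GL += v[k].second;
        if (v[k].first == v[k + 1].first) continue;
        int nl = k + 1, nr = n - nl;
        if (nl < min_child || nr < min_child) continue;
        double GR = G - GL;
        double gain = GL * GL / (nl + lambda) + GR * GR / (nr + lambda) - base;
        if (gain > best_gain + 1e-12) {
          best_gain = gain;
          best_feat = f;
          best_thr = 0.5 * (v[k].first + v[k + 1].first);
        }
      }
    }
  }

  if (best_feat < 0) {
    nodes[node_id].feature = -1;
    nodes[node_id].value = -G / (H + lambda);
    return;
  }

  int mid = lo;
  for (int k = lo; k < hi; ++k)
    if (X(idx[k], best_feat) < best_thr) std::swap(idx[k], idx[mid++]);
  if (mid == lo || mid == hi) {  // numeric degeneracy; fall back to leaf
    nodes[node_id].feature = -1;
    nodes[node_id].value = -G / (H + lambda);
    return;
  }

  nodes[node_id].feature = best_feat;
  nodes[node_id].threshold = best_thr;
  int l = (int)nodes.size(); nodes.push_back(Node());
  int r = (int)nodes.size(); nodes.push_back(Node());
  nodes[node_id].left = l;
  nodes[node_id].right = r;
  grow(nodes, l, X, grad, idx, lo, mid, depth + 1, max_depth, lambda, min_child);
  grow(nodes, r, X, grad, idx, mid, hi, depth + 1, max_depth, lambda, min_child);
}

static inline double tree_predict(const NumericMatrix &tree, double *x) {
  int node = 0;
  while (tree(node, 0) >= 0) {
    int f = (int)tree(node, 0);
    node = (x[f] < tree(node, 1)) ? (int)tree(node, 2) : (int)tree(node, 3);
  }
  return tree(node, 4);
}

// [[Rcpp::export(name = ".gbt_fit_cpp")]]
List gbt_fit_cpp(NumericMatrix X, NumericVector y, int n_trees,
                 double learning_rate, int max_depth, double lambda,
                 int min_child) {
  const int n = X.nrow();
  double base = Rcpp::mean(y);
  std::vector<double> pred(n, base), grad(n);
  List trees(n_trees);

  for (int t = 0; t < n_trees; ++t) {
    for (int i = 0; i < n; ++i) grad[i] = pred[i] - y[i];
    std::vector<Node> nodes(1);
    std::vector<int> idx(n);
    for (int i = 0; i < n; ++i) idx[i] = i;
    grow(nodes, 0, X, grad, idx, 0, n, 0, max_depth, lambda, min_child);

    NumericMatrix tm((int)nodes.size(), 5);
    for (size_t k = 0; k < nodes.size(); ++k) {
      tm(k, 0) = nodes[k].feature;
      tm(k, 1) = nodes[k].threshold;
      tm(k, 2) = nodes[k].left;
      tm(k, 3) = nodes[k].right;
      tm(k, 4) = nodes[k].value;
    }
    trees[t] = tm;

    std::vector<double> row(X.ncol());
    for (int i = 0; i < n; ++i) {
      for (int f = 0; f < X.ncol(); ++f) row[f] = X(i, f);
      pred[i] += learning_rate * tree_predict(tm, row.data());
    }
  }
  return List::create(_["base_score"] = base, _["trees"] = trees,
                      _["learning_rate"] = learning_rate);
}

// [[Rcpp::export(name = ".gbt_predict_cpp")]]
NumericVector gbt_predict_cpp(List booster, NumericMatrix X) {
  const int n = X.nrow(), p = X.ncol();
  double base = as<double>(booster["base_score"]);
  double eta = as<double>(booster["learning_rate"]);
  List trees = booster["trees"];
  NumericVector out(n, base);
  std::vector<double> row(p);
  for (int i = 0; i < n; ++i) {
    for (int f = 0; f < p; ++f) row[f] = X(i, f);
    double acc = 0.0;
    for (int t = 0; t < trees.size(); ++t) {
      NumericMatrix tm = trees[t];
      acc += tree_predict(tm, row.data());
    }
    out[i] += eta * acc;
  }
  return out;
}
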