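// Exact greedy CART-style regression trees (squared-error criterion).
// The three completeness regressors (gradient boosting, AdaBoost.R2,
// random forest) are assembled in R on top of this fitter; randomness
// (bootstrap rows) is drawn on the R side so the C++ code is fully
// deterministic.

#include <Rcpp.h>
#include <algorithm>
#include <stack>
#include <vector>

using namespace Rcpp;

struct Task {
  std::vector<int> idx;  // row indices into X/y (may repeat: bootstrap)
  int depth;
  int parent;            // node index of parent, -1 for root
  bool is_left;
};

// [[Rcpp::export(name = ".fit_tree_cpp")]]
List fit_tree_cpp(NumericMatrix X, NumericVector y, IntegerVector rows,
                  int max_depth, int min_samples_split,
                  int min_samples_leaf) {
  const int p = X.ncol();

  std::vector<int> feature, left, right;
  std::vector<double> threshold, value;

  std::stack<Task> stack;
  Task root;
  root.idx.assign(rows.begin(), rows.end());
  root.depth = 0;
  root.parent = -1;
  root.is_left = false;
  stack.push(root);

  std::vector<std::pair<double, double> > xy;  // scratch: (x, y) sorted

  while (!stack.empty()) {
    Task t = stack.top();
    stack.pop();
    const int n = (int)t.idx.size();

    double sum = 0.0, sumsq = 0.0;
    for (int k = 0; k < n; ++k) {
      double yi = y[t.idx[k]];
      sum += yi;
      sumsq += yi * yi;
    }
    const double node_mean = sum / n;
    const double node_sse = sumsq - sum * sum / n;

    int best_feat = -1;
    double best_gain = 1e-12, best_thr = 0.0;

    bool splittable = (max_depth < 0 || t.depth < max_depth) &&
                      n >= min_samples_split && node_sse > 1e-12;
    if (splittable) {
      for (int j = 0; j < p; ++j) {
        xy.resize(n);
        for (int k = 0; k < n; ++k)
          xy[k] = std::make_pair(X(t.idx[k], j), y[t.idx[k]]);
        std::sort(xy.begin(), xy.end());
        if (xy.front().first == xy.back().first) continue;
        double sl = 0.0;
        for (int k = 0; k < n - 1; ++k) {
          sl += xy[k].second;
          if (xy[k].first == xy[k + 1].first) continue;
          const int nl = k + 1, nr = n - nl;
          if (nl < min_samples_leaf || nr < min_samples_leaf) continue;
          const double sr = sum - sl;
          const double gain =
              sl * sl / nl + sr * sr / nr - sum * sum / n;
          if (gain > best_gain * (1.0 + 1e-12) &&
              gain - best_gain > 1e-12) {
            best_gain = gain;
            best_feat = j;
            best_thr = 0.5 * (xy[k].first + xy[k + 1].first);
          }
        }
      }
    }

    const int me = (int)feature.size();
    if (t.parent >= 0) {
      if (t.is_left) left[t.parent] = me;
      else right[t.parent] = me;
    }

    if (best_feat < 0) {  // leaf
      feature.push_back(-1);
      threshold.push_back(0.0);
      left.push_back(-1);
      right.push_back(-1);
      value.push_back(node_mean);
      continue;
    }

    feature.push_back(best_feat);
    threshold.push_back(best_thr);
    left.push_back(-1);
    right.push_back(-1);
    value.push_back(node_mean);

    Task tl, tr;
    tl.depth = tr.depth = t.depth + 1;
    tl.parent = tr.parent = me;
    tl.is_left = true;
    tr.is_left = false;
    for (int k = 0; k < n; ++k) {
      if (X(t.idx[k], best_feat) <= best_thr) tl.idx.push_back(t.idx[k]);
      else tr.idx.push_back(t.idx[k]);
    }
    // push right first so the left child is materialised first (stable
    // node numbering across runs)
    stack.push(tr);
    stack.push(tl);
  }

  return List::create(_["feature"] = wrap(feature),
                      _["threshold"] = wrap(threshold),
                      _["left"] = wrap(left),
                      _["right"] = wrap(right),
                      _["value"] = wrap(value));
}

// [[Rcpp::export(name = ".predict_tree_cpp")]]
NumericVector predict_tree_cpp(List tree, NumericMatrix X) {
  IntegerVector feature = tree["feature"];
  NumericVector threshold = tree["threshold"];
  IntegerVector left = tree["left"];
  IntegerVector right = tree["right"];
  NumericVector value = tree["value"];

  const int n = X.nrow();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    int node = 0;
    while (feature[node] >= 0) {
      node = (X(i, feature[node]) <= threshold[node]) ? left[node]
                                                      : right[node];
    }
    out[i] = value[node];
  }
  return out;
}
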