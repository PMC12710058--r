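// Depth-limited weighted CART regression trees: exact greedy split search
// on the weighted squared-error criterion. The ensemble drivers (gradient
// boosting, AdaBoost.R2, random forest) live in R and call these builders.

#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

struct Node {
  int feature = -1;      // -1 for a leaf
  double threshold = 0;  // go left if x <= threshold
  int left = -1, right = -1;
  double value = 0;      // weighted mean of y in the node
  double cover = 0;      // sum of sample weights
};

struct Builder {
  const NumericMatrix& X;
  const NumericVector& y;
  const NumericVector& w;
  int max_depth, min_leaf;
  const std::vector<int>& features;  // candidate feature indices
  std::vector<Node> nodes;

  Builder(const NumericMatrix& X_, const NumericVector& y_,
          const NumericVector& w_, int max_depth_, int min_leaf_,
          const std::vector<int>& feats)
    : X(X_), y(y_), w(w_), max_depth(max_depth_), min_leaf(min_leaf_),
      features(feats) {}

  int build(std::vector<int>& idx, int depth) {
    double sw = 0, swy = 0;
    for (int i : idx) { sw += w[i]; swy += w[i] * y[i]; }
    Node nd;
    nd.cover = sw;
    nd.value = (sw > 0) ? swy / sw : 0.0;

    bool is_leaf = (depth >= max_depth) || ((int)idx.size() < 2 * min_leaf);
    int best_f = -1;
    double best_thr = 0, best_gain = 1e-12;

    if (!is_leaf) {
      // parent weighted SSE contribution: -swy^2/sw (constant part drops)
      double parent_score = (sw > 0) ? swy * swy / sw : 0.0;
      std::vector<std::pair<double, int>> vals(idx.size());
      for (int f : features) {
        for (size_t k = 0; k < idx.size(); ++k)
          vals[k] = { X(idx[k], f), idx[k] };
        std::sort(vals.begin(), vals.end());
        double lw = 0, lwy = 0;
        for (size_t k = 0; k + 1 < vals.size(); ++k) {
          int i = vals[k].second;
          lw += w[i]; lwy += w[i] * y[i];
          if (vals[k + 1].first <= vals[k].first) continue;  // tied values
          if ((int)(k + 1) < min_leaf || (int)(vals.size() - k - 1) < min_leaf)
            continue;
          double rw = sw - lw, rwy = swy - lwy;
          if (lw <= 0 || rw <= 0) continue;
          double gain = lwy * lwy / lw + rwy * rwy / rw - parent_score;
          if (gain > best_gain) {
            best_gain = gain;
            best_f = f;
            best_thr = 0.5 * (vals[k].first + vals[k + 1].first);
          }
        }
      }
    }

    int my_id = (int)nodes.size();
    nodes.push_back(nd);
    if (best_f >= 0) {
      std::vector<int> li, ri;
      li.reserve(idx.size()); ri.reserve(idx.size());
      for (int i : idx) {
        if (X(i, best_f) <= best_thr) li.push_back(i); else ri.push_back(i);
      }
      if (!li.empty() && !ri.empty()) {
        nodes[my_id].feature = best_f;
        nodes[my_id].threshold = best_thr;
        int l = build(li, depth + 1);
        int r = build(ri, depth + 1);
        nodes[my_id].left = l;
        nodes[my_id].right = r;
      }
    }
    return my_id;
  }
};

// [[Rcpp::export(name = ".tree_fit_cpp")]]
List tree_fit_cpp(NumericMatrix X, NumericVector y, NumericVector w,
                  int max_depth, int min_leaf, IntegerVector feature_subset) {
  std::vector<int> feats(feature_subset.begin(), feature_subset.end());
  Builder b(X, y, w, max_depth, min_leaf, feats);
  std::vector<int> idx(X.nrow());
  for (int i = 0; i < X.nrow(); ++i) idx[i] = i;
  b.build(idx, 0);
  int n = (int)b.nodes.size();
  IntegerVector feature(n), left(n), right(n);
  NumericVector threshold(n), value(n), cover(n);
  for (int i = 0; i < n; ++i) {
    feature[i] = b.nodes[i].feature;
    threshold[i] = b.nodes[i].threshold;
    left[i] = b.nodes[i].left;
    right[i] = b.nodes[i].right;
    value[i] = b.nodes[i].value;
    cover[i] = b.nodes[i].cover;
  }
  return List::create(_["feature"] = feature, _["threshold"] = threshold,
                      _["left"] = left, _["right"] = right,
                      _["value"] = value, _["cover"] = cover);
}

// [[Rcpp::export(name = ".tree_predict_cpp")]]
NumericVector tree_predict_cpp(List tree, NumericMatrix X) {
  IntegerVector feature = tree["feature"], left = tree["left"],
                right = tree["right"];
  NumericVector threshold = tree["threshold"], value = tree["value"];
  int n = X.nrow();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    int node = 0;
    while (feature[node] >= 0) {
      node = (X(i, feature[node]) <= threshold[node]) ? left[node] : right[node];
    }
    out[i] = value[node];
  }
  return out;
}

// Predict with masked features marginalized over a background matrix:
// for each explained row, features outside `active` are replaced by the
// background row's values; the prediction is averaged over all background
// rows. Used by the exact-Shapley explainer.
// [[Rcpp::export(name = ".tree_predict_masked_cpp")]]
NumericVector tree_predict_masked_cpp(List tree, NumericMatrix X,
                                      NumericMatrix bg, LogicalVector active) {
  IntegerVector feature = tree["feature"], left = tree["left"],
                right = tree["right"];
  NumericVector threshold = tree["threshold"], value = tree["value"];
  int n = X.nrow(), nb = bg.nrow();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    double acc = 0;
    for (int b = 0; b < nb; ++b) {
      int node = 0;
      while (feature[node] >= 0) {
        int f = feature[node];
        double xv = active[f] ? X(i, f) : bg(b, f);
        node = (xv <= threshold[node]) ? left[node] : right[node];
      }
      acc += value[node];
    }
    out[i] = acc / nb;
  }
  return out;
}
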