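// Regression random forest (CART variance-reduction splits, bootstrap
// resampling, feature subsampling per split). Uses R's RNG so that
// set.seed() in R makes fits reproducible.
#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <stack>
using namespace Rcpp;

namespace {

struct Node {
  int feature;     // -1 for leaf
  double threshold;
  int left, right; // node indices
  double value;    // mean response at node (prediction for leaves)
};

struct BuildItem {
  int node;
  int lo, hi;      // range in index buffer
  int depth;
};

// sample k of n without replacement (partial Fisher-Yates, R RNG)
void sample_features(std::vector<int>& pool, int k) {
  int n = pool.size();
  for (int i = 0; i < k; ++i) {
    int j = i + (int)(unif_rand() * (n - i));
    if (j >= n) j = n - 1;
    std::swap(pool[i], pool[j]);
  }
}

} // namespace

// [[Rcpp::export]]
List cpp_grow_forest(NumericMatrix X, NumericVector y, int n_trees, int mtry,
                     int min_split, int max_depth, bool bootstrap) {
  const int n = X.nrow(), p = X.ncol();
  List trees(n_trees);
  NumericVector importance(p);
  std::vector<int> pool(p);
  std::vector<int> idx(n);
  std::vector<double> xv(n);

  for (int t = 0; t < n_trees; ++t) {
    std::vector<int> rows(n);
    if (bootstrap) {
      for (int i = 0; i < n; ++i) {
        int j = (int)(unif_rand() * n);
        rows[i] = j >= n ? n - 1 : j;
      }
    } else {
      for (int i = 0; i < n; ++i) rows[i] = i;
    }

    std::vector<Node> nodes;
    nodes.reserve(2 * n);
    std::vector<int> buf(rows);
    std::stack<BuildItem> work;

    double s = 0;
    for (int i = 0; i < n; ++i) s += y[rows[i]];
    nodes.push_back({-1, 0.0, -1, -1, s / n});
    work.push({0, 0, n, 0});

    while (!work.empty()) {
      BuildItem it = work.top(); work.pop();
      int m = it.hi - it.lo;
      if (m < min_split || (max_depth > 0 && it.depth >= max_depth)) continue;

      double sum = 0, sum2 = 0;
      for (int i = it.lo; i < it.hi; ++i) {
        double v = y[buf[i]];
        sum += v; sum2 += v * v;
      }
      double sse_parent = sum2 - sum * sum / m;
      if (sse_parent <= 1e-12) continue;

      for (int j = 0; j < p; ++j) pool[j] = j;
      int k = std::min(mtry, p);
      sample_features(pool, k);

      double best_gain = 0, best_thr = 0;
      int best_feat = -1;

      for (int f = 0; f < k; ++f) {
        int feat = pool[f];
        for (int i = 0; i < m; ++i) {
          idx[i] = buf[it.lo + i];
          xv[i] = X(idx[i], feat);
        }
        std::vector<int> ord(m);
        for (int i = 0; i < m; ++i) ord[i] = i;
        std::sort(ord.begin(), ord.end(),
                  [&](int a, int b) { return xv[a] < xv[b]; });
        double sl = 0;
        for (int i = 0; i < m - 1; ++i) {
          sl += y[idx[ord[i]]];
          if (xv[ord[i + 1]] - xv[ord[i]] < 1e-12) continue;
          int nl = i + 1, nr = m - nl;
          double sr = sum - sl;
          double gain = sl * sl / nl + sr * sr / nr - sum * sum / m;
          if (gain > best_gain + 1e-12) {
            best_gain = gain;
            best_feat = feat;
            best_thr = 0.5 * (xv[ord[i]] + xv[ord[i + 1]]);
          }
        }
      }
      if (best_feat < 0) continue;

      int mid = it.lo;
      for (int i = it.lo; i < it.hi; ++i) {
        if (X(buf[i], best_feat) <= best_thr) std::swap(buf[mid++], buf[i]);
      }
      if (mid == it.lo || mid == it.hi) continue;

      double sl = 0;
      for (int i = it.lo; i < mid; ++i) sl += y[buf[i]];
      int nl = mid - it.lo, nr = it.hi - mid;

      int li = nodes.size();
      nodes.push_back({-1, 0.0, -1, -1, sl / nl});
      int ri = nodes.size();
      nodes.push_back({-1, 0.0, -1, -1, (sum - sl) / nr});
      Node& nd = nodes[it.node]; // nd0 may be stale after push_back
      nd.feature = best_feat;
      nd.threshold = best_thr;
      nd.left = li;
      nd.right = ri;
      importance[best_feat] += best_gain;
      work.push({li, it.lo, mid, it.depth + 1});
      work.push({ri, mid, it.hi, it.depth + 1});
    }

    int nn = nodes.size();
    NumericMatrix tm(nn, 5);
    for (int i = 0; i < nn; ++i) {
      tm(i, 0) = nodes[i].feature;
      tm(i, 1) = nodes[i].threshold;
      tm(i, 2) = nodes[i].left;
      tm(i, 3) = nodes[i].right;
      tm(i, 4) = nodes[i].value;
    }
    trees[t] = tm;
  }
  return List::create(_["trees"] = trees, _["importance"] = importance);
}

static inline double predict_tree(const NumericMatrix& tm,
                                  const NumericMatrix& X, int row) {
  int node = 0;
  while (tm(node, 0) >= 0) {
    node = (X(row, (int)tm(node, 0)) <= tm(node, 1)) ? (int)tm(node, 2)
                                                     : (int)tm(node, 3);
  }
  return tm(node, 4);
}

// [[Rcpp::export]]
NumericVector cpp_forest_predict(List trees, NumericMatrix X) {
  const int n = X.nrow(), T = trees.size();
  NumericVector out(n);
  for (int t = 0; t < T; ++t) {
    NumericMatrix tm = trees[t];
    for (int i = 0; i < n; ++i) out[i] += predict_tree(tm, X, i);
  }
  for (int i = 0; i < n; ++i) out[i] /= T;
  return out;
}

// Predictions summed over a subset of trees (1-based indices), divided by
// the TOTAL tree count: trees not splitting on a feature are invariant to
// it, so restricting to the trees that use both members of a pair leaves
// the 4-term Shapley interaction difference unchanged.
// [[Rcpp::export]]
NumericVector cpp_forest_predict_subset(List trees, NumericMatrix X,
                                        IntegerVector tree_idx) {
  const int n = X.nrow(), T = trees.size();
  NumericVector out(n);
  for (int k = 0; k < tree_idx.size(); ++k) {
    NumericMatrix tm = trees[tree_idx[k] - 1];
    for (int i = 0; i < n; ++i) out[i] += predict_tree(tm, X, i);
  }
  for (int i = 0; i < n; ++i) out[i] /= T;
  return out;
}

// 0-based feature ids used by each tree (for interaction screening)
// [[Rcpp::export]]
List cpp_forest_features(List trees) {
  const int T = trees.size();
  List out(T);
  for (int t = 0; t < T; ++t) {
    NumericMatrix tm = trees[t];
    std::vector<int> feats;
    for (int i = 0; i < tm.nrow(); ++i) {
      int f = (int)tm(i, 0);
      if (f >= 0) feats.push_back(f);
    }
    std::sort(feats.begin(), feats.end());
    feats.erase(std::unique(feats.begin(), feats.end()), feats.end());
    out[t] = IntegerVector(feats.begin(), feats.end());
  }
  return out;
}
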