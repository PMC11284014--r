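// Bagged regression trees with recorded bootstrap membership counts.
//
// Trees are grown on bootstrap resamples; at each node `mtry` candidate
// features are drawn without replacement and the best axis-aligned split by
// sum-of-squares reduction is taken. Leaves store the mean response of their
// in-bag observations. Per-sample bootstrap counts N[i][b] are kept so the
// infinitesimal-jackknife variance and out-of-bag predictions can be
// computed downstream. All randomness comes from a single 64-bit Mersenne
// Twister seeded from R, so results are reproducible across runs.

#include <Rcpp.h>
#include <random>
#include <algorithm>
#include <vector>
#include <cstdint>

using namespace Rcpp;

namespace {

// bounded draw in [0, n) with rejection to avoid modulo bias
inline int rand_below(std::mt19937_64& gen, int n) {
  const uint64_t limit = UINT64_MAX - (UINT64_MAX % (uint64_t)n);
  uint64_t x;
  do { x = gen(); } while (x >= limit);
  return (int)(x % (uint64_t)n);
}

struct TreeBuf {
  std::vector<int> feature;       // -1 for leaf
  std::vector<double> threshold;
  std::vector<int> left, right;   // 0-based child node ids, -1 for leaf
  std::vector<double> value;      // leaf mean (only meaningful at leaves)
  int new_node() {
    feature.push_back(-1); threshold.push_back(0.0);
    left.push_back(-1); right.push_back(-1); value.push_back(0.0);
    return (int)feature.size() - 1;
  }
};

struct Task { int node; int begin; int end; int depth; };

void grow_tree(const double* X, const double* y, int n_rows, int p,
               std::vector<int>& idx,  // expanded bootstrap indices
               int mtry, int min_node, int max_depth,
               std::mt19937_64& gen, TreeBuf& tb) {
  std::vector<int> feat_pool(p);
  std::vector<int> cand(mtry);
  std::vector<std::pair<double, double>> xy;

  int root = tb.new_node();
  std::vector<Task> stack;
  stack.push_back({root, 0, (int)idx.size(), 0});

  while (!stack.empty()) {
    Task tk = stack.back(); stack.pop_back();
    const int n_node = tk.end - tk.begin;

    double sum = 0.0, sumsq = 0.0;
    for (int k = tk.begin; k < tk.end; ++k) {
      const double v = y[idx[k]];
      sum += v; sumsq += v * v;
    }
    const double mean = sum / n_node;
    tb.value[tk.node] = mean;

    const bool pure = (sumsq - sum * mean) <= 1e-10 * std::max(1.0, sumsq);
    if (n_node <= min_node || pure ||
        (max_depth > 0 && tk.depth >= max_depth)) {
      continue;  // leaf
    }

    // sample mtry distinct features, then visit in ascending index order
    // so split ties resolve to the lowest feature index deterministically
    for (int j = 0; j < p; ++j) feat_pool[j] = j;
    for (int j = 0; j < mtry; ++j) {
      int r = j + rand_below(gen, p - j);
      std::swap(feat_pool[j], feat_pool[r]);
      cand[j] = feat_pool[j];
    }
    std::sort(cand.begin(), cand.end());

    int best_feat = -1;
    double best_thr = 0.0;
    const double base = sum * sum / n_node;
    double best_score = base + 1e-9 * std::max(1.0, std::abs(base));

    for (int j = 0; j < mtry; ++j) {
      const int f = cand[j];
      const double* xf = X + (size_t)f * n_rows;
      xy.clear();
      for (int k = tk.begin; k < tk.end; ++k) {
        xy.emplace_back(xf[idx[k]], y[idx[k]]);
      }
      std::sort(xy.begin(), xy.end());
      if (xy.front().first == xy.back().first) continue;
      double lsum = 0.0;
      for (int k = 0; k + 1 < n_node; ++k) {
        lsum += xy[k].second;
        if (xy[k + 1].first > xy[k].first) {
          const int nl = k + 1, nr = n_node - nl;
          const double rsum = sum - lsum;
          const double score = lsum * lsum / nl + rsum * rsum / nr;
          if (score > best_score) {  // strict: ties keep earlier feature,
            best_score = score;      // lower threshold
            best_feat = f;
            best_thr = (xy[k].first + xy[k + 1].first) / 2.0;
          }
        }
      }
    }

    if (best_feat < 0) continue;  // no informative split among candidates

    // partition idx[begin, end) by x <= threshold
    const double* xb = X + (size_t)best_feat * n_rows;
    int lo = tk.begin, hi = tk.end - 1;
    while (lo <= hi) {
      if (xb[idx[lo]] <= best_thr) { ++lo; }
      else { std::swap(idx[lo], idx[hi]); --hi; }
    }
    const int mid = lo;
    if (mid == tk.begin || mid == tk.end) continue;  // degenerate, keep leaf

    tb.feature[tk.node] = best_feat;
    tb.threshold[tk.node] = best_thr;
    const int lch = tb.new_node();
    const int rch = tb.new_node();
    tb.left[tk.node] = lch;
    tb.right[tk.node] = rch;
    stack.push_back({rch, mid, tk.end, tk.depth + 1});
    stack.push_back({lch, tk.begin, mid, tk.depth + 1});
  }
}

}  // namespace

// [[Rcpp::export(name = ".grow_forest_cpp")]]
List grow_forest_cpp(NumericMatrix X, NumericVector y, int n_trees,
                     int mtry, int min_node_size, int max_depth,
                     double seed) {
  const int n = X.nrow();
  const int p = X.ncol();
  std::mt19937_64 gen((uint64_t)seed);
  IntegerMatrix N(n, n_trees);
  List trees(n_trees);
  std::vector<int> idx(n);
  const double* xp = &X[0];
  const double* yp = &y[0];

  for (int b = 0; b < n_trees; ++b) {
    for (int i = 0; i < n; ++i) {
      int d = rand_below(gen, n);
      idx[i] = d;
      N(d, b) += 1;
    }
    TreeBuf tb;
    grow_tree(xp, yp, n, p, idx, mtry, min_node_size, max_depth, gen, tb);
    trees[b] = List::create(
      _["feature"] = IntegerVector(tb.feature.begin(), tb.feature.end()),
      _["threshold"] = NumericVector(tb.threshold.begin(), tb.threshold.end()),
      _["left"] = IntegerVector(tb.left.begin(), tb.left.end()),
      _["right"] = IntegerVector(tb.right.begin(), tb.right.end()),
      _["value"] = NumericVector(tb.value.begin(), tb.value.end()));
  }
  return List::create(_["trees"] = trees, _["N"] = N);
}

// per-tree predictions: rows = observations of X, cols = trees
// [[Rcpp::export(name = ".predict_forest_cpp")]]
NumericMatrix predict_forest_cpp(List trees, NumericMatrix X) {
  const int n = X.nrow();
  const int B = trees.size();
  NumericMatrix out(n, B);
  for (int b = 0; b < B; ++b) {
    List tr = trees[b];
    IntegerVector feature = tr["feature"];
    NumericVector threshold = tr["threshold"];
    IntegerVector left = tr["left"];
    IntegerVector right = tr["right"];
    NumericVector value = tr["value"];
    for (int i = 0; i < n; ++i) {
      int node = 0;
      while (feature[node] >= 0) {
        node = (X(i, feature[node]) <= threshold[node])
                 ? left[node] : right[node];
      }
      out(i, b) = value[node];
    }
  }
  return out;
}
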