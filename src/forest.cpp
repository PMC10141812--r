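#include <Rcpp.h>
#include <algorithm>
#include <cstdint>
#include <random>
#include <vector>

using namespace Rcpp;

// Binary-classification CART forest: gini splits, bootstrap resampling,
// mtry features per node, impurity-decrease importance. All randomness
// comes from std::mt19937_64 seeded by the caller, so fits are
// reproducible across platforms and independent of R's RNG state.

namespace {

struct TreeNodes {
  std::vector<int> feature;       // -1 => leaf
  std::vector<double> threshold;  // go left if x <= threshold
  std::vector<int> left, right;
  std::vector<double> pred;       // leaf: P(class 1) among training rows
};

struct NodeJob {
  std::vector<int> idx;  // row indices (bootstrap, with multiplicity)
  int node_id;
  int depth;
};

inline double gini(double n0, double n1) {
  double n = n0 + n1;
  if (n <= 0.0) return 0.0;
  double p0 = n0 / n, p1 = n1 / n;
  return 1.0 - p0 * p0 - p1 * p1;
}

void build_tree(const NumericMatrix& x, const IntegerVector& y, int mtry,
                int min_node, int max_depth, std::mt19937_64& rng,
                TreeNodes& tree, std::vector<double>& importance,
                double n_total) {
  const int n = x.nrow(), p = x.ncol();

  // bootstrap sample
  std::uniform_int_distribution<int> row_dist(0, n - 1);
  std::vector<int> boot(n);
  for (int i = 0; i < n; ++i) boot[i] = row_dist(rng);

  std::vector<int> feat_pool(p);
  for (int j = 0; j < p; ++j) feat_pool[j] = j;

  std::vector<NodeJob> stack;
  tree.feature.push_back(-1);
  tree.threshold.push_back(0.0);
  tree.left.push_back(-1);
  tree.right.push_back(-1);
  tree.pred.push_back(0.0);
  stack.push_back(NodeJob{boot, 0, 0});

  std::vector<std::pair<double, int> > vals;  // (value, label)

  while (!stack.empty()) {
    NodeJob job = std::move(stack.back());
    stack.pop_back();
    const std::vector<int>& idx = job.idx;
    const int m = (int)idx.size();

    double c1 = 0.0;
    for (int i = 0; i < m; ++i) c1 += y[idx[i]];
    double c0 = m - c1;
    tree.pred[job.node_id] = (m > 0) ? c1 / m : 0.5;

    bool make_leaf = (c0 == 0.0 || c1 == 0.0 || m < 2 * min_node ||
                      (max_depth > 0 && job.depth >= max_depth));
    double best_gain = 0.0;
    int best_feat = -1;
    double best_thr = 0.0;
    double imp_parent = gini(c0, c1);

    if (!make_leaf) {
      // sample mtry distinct features (partial Fisher-Yates)
      for (int k = 0; k < mtry; ++k) {
        std::uniform_int_distribution<int> d(k, p - 1);
        std::swap(feat_pool[k], feat_pool[d(rng)]);
      }
      for (int k = 0; k < mtry; ++k) {
        int f = feat_pool[k];
        vals.clear();
        vals.reserve(m);
        for (int i = 0; i < m; ++i)
          vals.push_back(std::make_pair(x(idx[i], f), y[idx[i]]));
        std::sort(vals.begin(), vals.end());
        if (vals.front().first == vals.back().first) continue;
        double l0 = 0.0, l1 = 0.0;
        for (int i = 0; i + 1 < m; ++i) {
          if (vals[i].second == 1)
            l1 += 1.0;
          else
            l0 += 1.0;
          if (vals[i].first == vals[i + 1].first) continue;
          double r0 = c0 - l0, r1 = c1 - l1;
          double nl = l0 + l1, nr = r0 + r1;
          double gain =
              imp_parent - (nl / m) * gini(l0, l1) - (nr / m) * gini(r0, r1);
          if (gain > best_gain + 1e-12) {
            best_gain = gain;
            best_feat = f;
            best_thr = vals[i].first +
                       0.5 * (vals[i + 1].first - vals[i].first);
            // guard midpoint rounding to the upper value
            if (!(best_thr > vals[i].first && best_thr < vals[i + 1].first))
              best_thr = vals[i].first;
          }
        }
      }
    }

    if (best_feat < 0) {
      tree.feature[job.node_id] = -1;
      continue;
    }

    importance[best_feat] += ((double)m / n_total) * best_gain;

    std::vector<int> lidx, ridx;
    lidx.reserve(m);
    ridx.reserve(m);
    for (int i = 0; i < m; ++i) {
      if (x(idx[i], best_feat) <= best_thr)
        lidx.push_back(idx[i]);
      else
        ridx.push_back(idx[i]);
    }
    if (lidx.empty() || ridx.empty()) {  // numerically degenerate split
      tree.feature[job.node_id] = -1;
      continue;
    }

    int lid = (int)tree.feature.size();
    int rid = lid + 1;
    for (int t = 0; t < 2; ++t) {
      tree.feature.push_back(-1);
      tree.threshold.push_back(0.0);
      tree.left.push_back(-1);
      tree.right.push_back(-1);
      tree.pred.push_back(0.0);
    }
    tree.feature[job.node_id] = best_feat;
    tree.threshold[job.node_id] = best_thr;
    tree.left[job.node_id] = lid;
    tree.right[job.node_id] = rid;
    stack.push_back(NodeJob{std::move(ridx), rid, job.depth + 1});
    stack.push_back(NodeJob{std::move(lidx), lid, job.depth + 1});
  }
}

}  // namespace

// [[Rcpp::export(name = ".rf_train_cpp")]]
List rf_train_cpp(NumericMatrix x, IntegerVector y, int num_trees, int mtry,
                  int min_node, int max_depth, double seed) {
  const int p = x.ncol();
  std::mt19937_64 rng((std::uint64_t)seed);
  std::vector<double> importance(p, 0.0);
  List trees(num_trees);
  for (int t = 0; t < num_trees; ++t) {
    TreeNodes tr;
    build_tree(x, y, mtry, min_node, max_depth, rng, tr, importance,
               (double)x.nrow());
    trees[t] = List::create(_["feature"] = wrap(tr.feature),
                            _["threshold"] = wrap(tr.threshold),
                            _["left"] = wrap(tr.left),
                            _["right"] = wrap(tr.right),
                            _["pred"] = wrap(tr.pred));
  }
  double tot = 0.0;
  for (int j = 0; j < p; ++j) tot += importance[j];
  NumericVector imp(p);
  for (int j = 0; j < p; ++j)
    imp[j] = (tot > 0.0) ? importance[j] / tot : 1.0 / p;
  return List::create(_["trees"] = trees, _["importance"] = imp,
                      _["num_trees"] = num_trees);
}

// [[Rcpp::export(name = ".rf_predict_cpp")]]
NumericVector rf_predict_cpp(List forest, NumericMatrix x) {
  List trees = forest["trees"];
  const int n = x.nrow(), T = trees.size();
  NumericVector votes(n, 0.0);
  for (int t = 0; t < T; ++t) {
    List tr = trees[t];
    IntegerVector feature = tr["feature"];
    NumericVector threshold = tr["threshold"];
    IntegerVector left = tr["left"], right = tr["right"];
    NumericVector pred = tr["pred"];
    for (int i = 0; i < n; ++i) {
      int node = 0;
      while (feature[node] >= 0)
        node = (x(i, feature[node]) <= threshold[node]) ? left[node]
                                                        : right[node];
      votes[i] += (pred[node] > 0.5) ? 1.0 : 0.0;
    }
  }
  for (int i = 0; i < n; ++i) votes[i] /= T;
  return votes;  // fraction of trees voting class 1
}
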