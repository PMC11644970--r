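// Random forest for binary classification: bagged depth-limited CART trees
// with Gini splits and per-node random feature subsets. Kept deliberately
// small: the grids used here never exceed depth 3, so trees are tiny and
// the LOOCV grid search stays fast.

#include <Rcpp.h>
#include <random>
#include <algorithm>
#include <vector>

namespace {

struct Node {
  int feature = -1;        // -1: leaf
  double threshold = 0.0;
  int left = -1, right = -1;
  double prob1 = 0.0;      // class-1 fraction at the node
};

struct TreeBuilder {
  const Rcpp::NumericMatrix& X;
  const Rcpp::IntegerVector& y;
  int max_depth, min_split, min_leaf, mtry;
  std::mt19937& rng;
  std::vector<Node> nodes;

  TreeBuilder(const Rcpp::NumericMatrix& X, const Rcpp::IntegerVector& y,
              int max_depth, int min_split, int min_leaf, int mtry,
              std::mt19937& rng)
      : X(X), y(y), max_depth(max_depth), min_split(min_split),
        min_leaf(min_leaf), mtry(mtry), rng(rng) {}

  int build(std::vector<int>& idx, int depth) {
    int id = (int)nodes.size();
    nodes.push_back(Node());
    int n = (int)idx.size();
    int n1 = 0;
    for (int i : idx) n1 += y[i];
    nodes[id].prob1 = n > 0 ? (double)n1 / n : 0.0;
    if (depth >= max_depth || n < min_split || n1 == 0 || n1 == n ||
        n < 2 * min_leaf)
      return id;

    // sample mtry features without replacement (partial Fisher-Yates)
    int p = X.ncol();
    std::vector<int> feats(p);
    for (int j = 0; j < p; ++j) feats[j] = j;
    int m = std::min(mtry, p);
    for (int j = 0; j < m; ++j) {
      std::uniform_int_distribution<int> d(j, p - 1);
      std::swap(feats[j], feats[d(rng)]);
    }

    double best_imp = std::numeric_limits<double>::infinity();
    int best_f = -1;
    double best_thr = 0.0;
    std::vector<std::pair<double, int>> vals(n);
    for (int jj = 0; jj < m; ++jj) {
      int f = feats[jj];
      for (int k = 0; k < n; ++k) vals[k] = {X(idx[k], f), y[idx[k]]};
      std::sort(vals.begin(), vals.end());
      int left1 = 0;
      for (int k = 0; k < n - 1; ++k) {
        left1 += vals[k].second;
        if (vals[k].first == vals[k + 1].first) continue;
        int nl = k + 1, nr = n - nl;
        if (nl < min_leaf || nr < min_leaf) continue;
        double pl = (double)left1 / nl, pr = (double)(n1 - left1) / nr;
        double imp = nl * 2.0 * pl * (1 - pl) + nr * 2.0 * pr * (1 - pr);
        if (imp < best_imp - 1e-12) {
          best_imp = imp;
          best_f = f;
          best_thr = 0.5 * (vals[k].first + vals[k + 1].first);
        }
      }
    }
    if (best_f < 0) return id;

    std::vector<int> li, ri;
    for (int i : idx)
      (X(i, best_f) <= best_thr ? li : ri).push_back(i);
    if ((int)li.size() < min_leaf || (int)ri.size() < min_leaf) return id;
    nodes[id].feature = best_f;
    nodes[id].threshold = best_thr;
    nodes[id].left = build(li, depth + 1);
    nodes[id].right = build(ri, depth + 1);
    return id;
  }

  double predict(const Rcpp::NumericMatrix& Xt, int row) const {
    int cur = 0;
    while (nodes[cur].feature >= 0)
      cur = Xt(row, nodes[cur].feature) <= nodes[cur].threshold
                ? nodes[cur].left
                : nodes[cur].right;
    return nodes[cur].prob1;
  }
};

}  // namespace

// [[Rcpp::export(name = ".rf_train_predict")]]
Rcpp::NumericVector rf_train_predict(Rcpp::NumericMatrix Xtr,
                                     Rcpp::IntegerVector ytr,
                                     Rcpp::NumericMatrix Xte, int n_trees,
                                     int max_depth, int min_split,
                                     int min_leaf, int mtry, int seed) {
  int n = Xtr.nrow(), nt = Xte.nrow();
  Rcpp::NumericVector out(nt, 0.0);
  std::mt19937 rng((unsigned)seed);
  std::uniform_int_distribution<int> boot(0, n - 1);
  std::vector<int> idx(n);
  for (int t = 0; t < n_trees; ++t) {
    for (int i = 0; i < n; ++i) idx[i] = boot(rng);
    TreeBuilder tb(Xtr, ytr, max_depth, min_split, min_leaf, mtry, rng);
    tb.build(idx, 0);
    for (int r = 0; r < nt; ++r) out[r] += tb.predict(Xte, r);
  }
  for (int r = 0; r < nt; ++r) out[r] /= n_trees;
  return out;
}

// Full LOOCV x grid evaluation in one call: returns a matrix of class-1
// probabilities for each held-out sample, one row per (structural config,
// tree-count checkpoint) pair in config-major order. Tree counts nest: the
// first k trees of a forest are themselves a valid k-tree forest, so all
// checkpoints share one pass. Feature presort is shared across folds,
// configs and trees.
// [[Rcpp::export(name = ".rf_grid_loocv")]]
Rcpp::NumericMatrix rf_grid_loocv(Rcpp::NumericMatrix X,
                                  Rcpp::IntegerVector y,
                                  Rcpp::IntegerVector checkpoints,
                                  Rcpp::IntegerVector max_depth,
                                  Rcpp::IntegerVector min_split,
                                  Rcpp::IntegerVector min_leaf,
                                  Rcpp::IntegerVector mtry, int seed) {
  int n = X.nrow(), p = X.ncol(), ncfg = max_depth.size();
  int nck = checkpoints.size();
  int max_trees = checkpoints[nck - 1];
  Rcpp::NumericMatrix out(ncfg * nck, n);

  // global presort of each feature
  std::vector<std::vector<int>> order(p, std::vector<int>(n));
  for (int j = 0; j < p; ++j) {
    for (int i = 0; i < n; ++i) order[j][i] = i;
    const double* col = &X(0, j);
    std::sort(order[j].begin(), order[j].end(),
              [col](int a, int b) { return col[a] < col[b]; });
  }

  std::vector<int> boot(n), node_of(n), feats(p);
  struct SNode { int feature, left, right; double threshold, prob1; };
  std::vector<SNode> nodes;

  for (int fold = 0; fold < n; ++fold) {
    for (int cfg = 0; cfg < ncfg; ++cfg) {
      std::mt19937 rng((unsigned)(seed + 7919 * cfg + fold));
      std::uniform_int_distribution<int> pick(0, n - 2);
      double acc = 0.0;
      int ck = 0;
      int dep = max_depth[cfg], msp = min_split[cfg],
          mlf = min_leaf[cfg], mt = std::min(mtry[cfg], p);
      for (int t = 0; t < max_trees; ++t) {
        // bootstrap over training rows (skip the held-out row)
        std::fill(boot.begin(), boot.end(), 0);
        for (int i = 0; i < n - 1; ++i) {
          int r = pick(rng);
          if (r >= fold) ++r;
          ++boot[r];
        }
        std::fill(node_of.begin(), node_of.end(), -1);
        for (int i = 0; i < n; ++i) if (boot[i]) node_of[i] = 0;
        nodes.clear();
        // breadth-first growth; member counts ride along in the queue
        struct Work { int id, depth, ntot, n1; };
        std::vector<Work> queue;
        nodes.push_back(SNode{-1, -1, -1, 0.0, 0.0});
        {
          int ntot0 = 0, n10 = 0;
          for (int i = 0; i < n; ++i)
            if (boot[i]) { ntot0 += boot[i]; n10 += boot[i] * y[i]; }
          queue.push_back({0, 0, ntot0, n10});
        }
        for (size_t qi = 0; qi < queue.size(); ++qi) {
          int id = queue[qi].id, depth = queue[qi].depth;
          int ntot = queue[qi].ntot, n1 = queue[qi].n1;
          nodes[id].prob1 = ntot ? (double)n1 / ntot : 0.0;
          if (depth >= dep || ntot < msp || n1 == 0 || n1 == ntot ||
              ntot < 2 * mlf)
            continue;
          // sample mtry features
          for (int j = 0; j < p; ++j) feats[j] = j;
          for (int j = 0; j < mt; ++j) {
            std::uniform_int_distribution<int> d(j, p - 1);
            std::swap(feats[j], feats[d(rng)]);
          }
          double best_imp = std::numeric_limits<double>::infinity();
          int best_f = -1; double best_thr = 0.0;
          for (int jj = 0; jj < mt; ++jj) {
            int f = feats[jj];
            const double* col = &X(0, f);
            int left = 0, left1 = 0, prev = -1;
            for (int oi = 0; oi < n; ++oi) {
              int i = order[f][oi];
              if (node_of[i] != id) continue;
              if (prev >= 0 && col[i] > col[prev]) {
                int nl = left, nr = ntot - left;
                if (nl >= mlf && nr >= mlf) {
                  double pl = (double)left1 / nl,
                         pr = (double)(n1 - left1) / nr;
                  double imp = nl * 2.0 * pl * (1 - pl) +
                               nr * 2.0 * pr * (1 - pr);
                  if (imp < best_imp - 1e-12) {
                    best_imp = imp; best_f = f;
                    best_thr = 0.5 * (col[prev] + col[i]);
                  }
                }
              }
              left += boot[i]; left1 += boot[i] * y[i];
              prev = i;
            }
          }
          if (best_f < 0) continue;
          int li = (int)nodes.size(), ri = li + 1;
          nodes.push_back(SNode{-1, -1, -1, 0.0, 0.0});
          nodes.push_back(SNode{-1, -1, -1, 0.0, 0.0});
          nodes[id].feature = best_f; nodes[id].threshold = best_thr;
          nodes[id].left = li; nodes[id].right = ri;
          int cl = 0, cr = 0, cl1 = 0;
          for (int i = 0; i < n; ++i)
            if (node_of[i] == id) {
              bool goleft = X(i, best_f) <= best_thr;
              node_of[i] = goleft ? li : ri;
              if (goleft) { cl += boot[i]; cl1 += boot[i] * y[i]; }
              else cr += boot[i];
            }
          if (cl < mlf || cr < mlf) {
            // revert (can happen only via bootstrap weighting quirks)
            for (int i = 0; i < n; ++i)
              if (node_of[i] == li || node_of[i] == ri) node_of[i] = id;
            nodes[id].feature = -1; nodes.resize(li);
            continue;
          }
          queue.push_back({li, depth + 1, cl, cl1});
          queue.push_back({ri, depth + 1, cr, n1 - cl1});
        }
        // predict held-out row
        int cur = 0;
        while (nodes[cur].feature >= 0)
          cur = X(fold, nodes[cur].feature) <= nodes[cur].threshold
                    ? nodes[cur].left : nodes[cur].right;
        acc += nodes[cur].prob1;
        if (t + 1 == checkpoints[ck]) {
          out(cfg * nck + ck, fold) = acc / (t + 1);
          ++ck;
        }
      }
    }
  }
  return out;
}
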