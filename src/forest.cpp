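// A small CART-based random forest for classification.
//
// Trees are grown on bootstrap samples with Gini impurity, a random feature
// subset at every split (mtry), optional depth limit and per-class case
// weights. Predictions average the class proportions of the terminal leaves.
// Variable importance is the total (weighted) impurity decrease attributed to
// each feature, divided by the number of trees. All randomness comes from a
// std::mt19937 seeded from R, so results are reproducible across platforms.
#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <random>
using namespace Rcpp;

struct TreeNodes {
  std::vector<int> feature;      // -1 for leaf
  std::vector<double> threshold; // go left if x <= threshold
  std::vector<int> left, right;
  std::vector<std::vector<double> > probs; // leaf class proportions
};

static double gini(const std::vector<double>& wc, double W) {
  if (W <= 0) return 0.0;
  double s = 0.0;
  for (size_t c = 0; c < wc.size(); ++c) { double p = wc[c] / W; s += p * p; }
  return 1.0 - s;
}

struct Grower {
  const NumericMatrix& x;
  const IntegerVector& y;
  int K, mtry, max_depth, min_node;
  const std::vector<double>& cw; // class weights
  std::mt19937& rng;
  std::vector<double>& importance;
  TreeNodes tree;
  std::vector<int> feat_pool;

  Grower(const NumericMatrix& x_, const IntegerVector& y_, int K_, int mtry_,
         int max_depth_, int min_node_, const std::vector<double>& cw_,
         std::mt19937& rng_, std::vector<double>& imp_)
      : x(x_), y(y_), K(K_), mtry(mtry_), max_depth(max_depth_),
        min_node(min_node_), cw(cw_), rng(rng_), importance(imp_) {
    feat_pool.resize(x.ncol());
    for (int j = 0; j < x.ncol(); ++j) feat_pool[j] = j;
  }

  int make_leaf(const std::vector<double>& wc, double W) {
    int id = (int)tree.feature.size();
    tree.feature.push_back(-1);
    tree.threshold.push_back(0.0);
    tree.left.push_back(-1);
    tree.right.push_back(-1);
    std::vector<double> p(K, 0.0);
    if (W > 0) for (int c = 0; c < K; ++c) p[c] = wc[c] / W;
    tree.probs.push_back(p);
    return id;
  }

  int grow(std::vector<int>& idx, int lo, int hi, int depth) {
    int n = hi - lo;
    std::vector<double> wc(K, 0.0);
    double W = 0.0;
    for (int t = lo; t < hi; ++t) { wc[y[idx[t]]] += cw[y[idx[t]]]; W += cw[y[idx[t]]]; }
    int nclass = 0;
    for (int c = 0; c < K; ++c) if (wc[c] > 0) ++nclass;
    double G = gini(wc, W);
    if (nclass <= 1 || n < 2 * min_node ||
        (max_depth > 0 && depth >= max_depth))
      return make_leaf(wc, W);

    // sample mtry features without replacement (partial Fisher-Yates)
    int p = (int)feat_pool.size();
    int m = std::min(mtry, p);
    for (int k = 0; k < m; ++k) {
      std::uniform_int_distribution<int> U(k, p - 1);
      std::swap(feat_pool[k], feat_pool[U(rng)]);
    }

    double best_gain = 1e-12;
    int best_f = -1;
    double best_thr = 0.0;
    std::vector<std::pair<double, int> > vals(n);
    std::vector<double> wl(K);
    for (int k = 0; k < m; ++k) {
      int f = feat_pool[k];
      for (int t = 0; t < n; ++t)
        vals[t] = std::make_pair(x(idx[lo + t], f), y[idx[lo + t]]);
      std::sort(vals.begin(), vals.end());
      if (vals.front().first == vals.back().first) continue;
      std::fill(wl.begin(), wl.end(), 0.0);
      double WL = 0.0;
      for (int t = 0; t < n - 1; ++t) {
        wl[vals[t].second] += cw[vals[t].second];
        WL += cw[vals[t].second];
        if (vals[t].first == vals[t + 1].first) continue;
        double WR = W - WL;
        double gl = gini(wl, WL);
        std::vector<double> wr(K);
        for (int c = 0; c < K; ++c) wr[c] = wc[c] - wl[c];
        double gr = gini(wr, WR);
        double gain = G - (WL * gl + WR * gr) / W;
        if (gain > best_gain) {
          best_gain = gain;
          best_f = f;
          best_thr = 0.5 * (vals[t].first + vals[t + 1].first);
        }
      }
    }
    if (best_f < 0) return make_leaf(wc, W);

    // partition idx[lo,hi) in place (stable enough for determinism)
    std::vector<int> lft, rgt;
    lft.reserve(n); rgt.reserve(n);
    for (int t = lo; t < hi; ++t)
      (x(idx[t], best_f) <= best_thr ? lft : rgt).push_back(idx[t]);
    if (lft.empty() || rgt.empty()) return make_leaf(wc, W);
    std::copy(lft.begin(), lft.end(), idx.begin() + lo);
    std::copy(rgt.begin(), rgt.end(), idx.begin() + lo + lft.size());

    importance[best_f] += best_gain * W;

    int id = (int)tree.feature.size();
    tree.feature.push_back(best_f);
    tree.threshold.push_back(best_thr);
    tree.left.push_back(-2);
    tree.right.push_back(-2);
    tree.probs.push_back(std::vector<double>());
    int mid = lo + (int)lft.size();
    int lid = grow(idx, lo, mid, depth + 1);
    int rid = grow(idx, mid, hi, depth + 1);
    tree.left[id] = lid;
    tree.right[id] = rid;
    return id;
  }
};

// [[Rcpp::export]]
List rf_train_cpp(NumericMatrix x, IntegerVector y, int n_class, int n_trees,
                  int mtry, int max_depth, int min_node,
                  NumericVector class_weights, int seed) {
  int n = x.nrow(), p = x.ncol();
  std::vector<double> cw(class_weights.begin(), class_weights.end());
  std::vector<double> importance(p, 0.0);
  std::mt19937 rng((unsigned)seed);
  List trees(n_trees);
  std::uniform_int_distribution<int> boot(0, n - 1);
  for (int b = 0; b < n_trees; ++b) {
    std::vector<int> idx(n);
    for (int t = 0; t < n; ++t) idx[t] = boot(rng);
    Grower g(x, y, n_class, mtry, max_depth, min_node, cw, rng, importance);
    g.grow(idx, 0, n, 0);
    int nn = (int)g.tree.feature.size();
    NumericMatrix pr(nn, n_class);
    for (int i = 0; i < nn; ++i)
      if (g.tree.feature[i] < 0)
        for (int c = 0; c < n_class; ++c) pr(i, c) = g.tree.probs[i][c];
    trees[b] = List::create(_["feature"] = wrap(g.tree.feature),
                            _["threshold"] = wrap(g.tree.threshold),
                            _["left"] = wrap(g.tree.left),
                            _["right"] = wrap(g.tree.right),
                            _["probs"] = pr);
  }
  NumericVector imp(p);
  for (int j = 0; j < p; ++j) imp[j] = importance[j] / n_trees;
  return List::create(_["trees"] = trees, _["importance"] = imp);
}

// [[Rcpp::export]]
NumericMatrix rf_predict_cpp(List trees, NumericMatrix x, int n_class) {
  int n = x.nrow(), B = trees.size();
  NumericMatrix out(n, n_class);
  for (int b = 0; b < B; ++b) {
    List tr = trees[b];
    IntegerVector feature = tr["feature"];
    NumericVector threshold = tr["threshold"];
    IntegerVector left = tr["left"], right = tr["right"];
    NumericMatrix probs = tr["probs"];
    for (int i = 0; i < n; ++i) {
      int node = 0;
      while (feature[node] >= 0)
        node = (x(i, feature[node]) <= threshold[node]) ? left[node] : right[node];
      for (int c = 0; c < n_class; ++c) out(i, c) += probs(node, c);
    }
  }
  for (int i = 0; i < n; ++i)
    for (int c = 0; c < n_class; ++c) out(i, c) /= B;
  return out;
}
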