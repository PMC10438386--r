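// Regression random forest recording per-split improvements, out-of-bag
// predictions and (cluster-conditional) permutation importance.  Written
// for the allelic-turnover aggregation, which needs the location and size
// of every split along each predictor.  Trees are grown on presorted
// per-variable index lists carried down the recursion, so no sorting
// happens inside nodes.  Uses R's RNG: results are reproducible under
// set.seed().

#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

namespace {

inline int rand_int(int n) {
  int k = (int)(unif_rand() * n);
  return k >= n ? n - 1 : k;
}

struct Forest {
  // flat node storage across all trees
  std::vector<int> var;      // -1 for leaf
  std::vector<double> thr;
  std::vector<int> left, right;
  std::vector<double> pred;
  std::vector<int> root;     // root node id per tree

  int new_node(double mean) {
    var.push_back(-1);
    thr.push_back(0.0);
    left.push_back(-1);
    right.push_back(-1);
    pred.push_back(mean);
    return (int)var.size() - 1;
  }
};

class Builder {
public:
  // lists_: arena of p index arrays (bootstrap sample, each sorted by its
  // variable); the recursion works on [lo, hi) segments of every array,
  // partitioning them in place with one scratch buffer — no allocation
  // inside the recursion.
  Builder(const std::vector<double>& X, const std::vector<double>& y, int n,
          int p, int mtry, int min_node, int max_depth, Forest& forest,
          std::vector<double>& split_var_thr_imp,
          std::vector<std::vector<int>>& lists)
      : X_(X), y_(y), n_(n), p_(p), mtry_(mtry), min_node_(min_node),
        max_depth_(max_depth), forest_(forest), splits_(split_var_thr_imp),
        lists_(lists) {
    vars_.resize(p_);
    tmp_.resize(lists[0].size());
  }

  int grow(int lo, int hi, int depth) {
    const int* l0 = lists_[0].data();
    int m = hi - lo;
    double s = 0.0, s2 = 0.0;
    for (int k = lo; k < hi; ++k) {
      double yv = y_[l0[k]];
      s += yv;
      s2 += yv * yv;
    }
    int me = forest_.new_node(s / m);
    double sse = s2 - s * s / m;
    if (m <= min_node_ || sse <= 1e-12 || depth >= max_depth_) return me;

    for (int j = 0; j < p_; ++j) vars_[j] = j;
    int ncand = std::min(mtry_, p_);
    for (int j = 0; j < ncand; ++j) std::swap(vars_[j], vars_[j + rand_int(p_ - j)]);

    int best_var = -1;
    double best_thr = 0.0, best_gain = 1e-12;
    for (int c = 0; c < ncand; ++c) {
      int v = vars_[c];
      const int* lv = lists_[v].data();
      const double* xv = &X_[(size_t)v * n_];
      double sl = 0.0;
      for (int k = lo; k < hi - 1; ++k) {
        sl += y_[lv[k]];
        double x0 = xv[lv[k]], x1 = xv[lv[k + 1]];
        if (x1 <= x0) continue;  // tied x, no cut here
        int nl = k - lo + 1, nr = m - nl;
        double sr = s - sl;
        double gain = sl * sl / nl + sr * sr / nr - s * s / m;
        if (gain > best_gain) {
          best_gain = gain;
          best_var = v;
          best_thr = 0.5 * (x0 + x1);
        }
      }
    }
    if (best_var < 0) return me;

    // stable in-place partition of every variable's segment
    const double* xb = &X_[(size_t)best_var * n_];
    int nl = 0;
    for (int v = 0; v < p_; ++v) {
      int* lv = lists_[v].data();
      int a = lo, b = 0;
      for (int k = lo; k < hi; ++k) {
        if (xb[lv[k]] <= best_thr) lv[a++] = lv[k];
        else tmp_[b++] = lv[k];
      }
      for (int k = 0; k < b; ++k) lv[a + k] = tmp_[k];
      nl = hi - lo - b;
    }
    if (nl == 0 || nl == m) return me;

    splits_.push_back((double)best_var);
    splits_.push_back(best_thr);
    splits_.push_back(best_gain);
    forest_.var[me] = best_var;
    forest_.thr[me] = best_thr;
    int lid = grow(lo, lo + nl, depth + 1);
    forest_.left[me] = lid;
    int rid = grow(lo + nl, hi, depth + 1);
    forest_.right[me] = rid;
    return me;
  }

private:
  const std::vector<double>& X_;
  const std::vector<double>& y_;
  int n_, p_, mtry_, min_node_, max_depth_;
  Forest& forest_;
  std::vector<double>& splits_;
  std::vector<std::vector<int>>& lists_;
  std::vector<int> vars_;
  std::vector<int> tmp_;
};

inline double predict_tree(const Forest& f, int node, const double* X, int n,
                           int i, const double* override_col, int override_v) {
  while (f.var[node] >= 0) {
    int v = f.var[node];
    double x = (v == override_v && override_col) ? override_col[i]
                                                 : X[(size_t)v * n + i];
    node = (x <= f.thr[node]) ? f.left[node] : f.right[node];
  }
  return f.pred[node];
}

}  // namespace

// [[Rcpp::export(name = ".rf_fit")]]
List rf_fit(NumericMatrix Xin, NumericVector yin, int n_trees, int mtry,
            int min_node, IntegerMatrix obs_group, int max_depth = 30) {
  RNGScope scope;
  const int n = Xin.nrow(), p = Xin.ncol();
  std::vector<double> X(Xin.begin(), Xin.end());  // column-major copy
  std::vector<double> y(yin.begin(), yin.end());

  // presort sample indices once per variable
  std::vector<std::vector<int>> order(p, std::vector<int>(n));
  for (int v = 0; v < p; ++v) {
    std::vector<int>& o = order[v];
    for (int i = 0; i < n; ++i) o[i] = i;
    const double* xv = &X[(size_t)v * n];
    std::stable_sort(o.begin(), o.end(),
                     [xv](int a, int b) { return xv[a] < xv[b]; });
  }

  Forest forest;
  std::vector<double> splits;  // triples (var, thr, gain)
  std::vector<std::vector<int>> tree_oob(n_trees);

  std::vector<int> count(n);
  for (int t = 0; t < n_trees; ++t) {
    std::fill(count.begin(), count.end(), 0);
    for (int k = 0; k < n; ++k) count[rand_int(n)]++;

    std::vector<std::vector<int>> lists(p);
    for (int v = 0; v < p; ++v) {
      lists[v].reserve(n);
      for (int i : order[v])
        for (int c = 0; c < count[i]; ++c) lists[v].push_back(i);
    }
    Builder b(X, y, n, p, mtry, min_node, max_depth, forest, splits, lists);
    forest.root.push_back(b.grow(0, (int)lists[0].size(), 0));
    for (int i = 0; i < n; ++i)
      if (count[i] == 0) tree_oob[t].push_back(i);
  }

  // out-of-bag predictions
  NumericVector oob_pred(n, NA_REAL);
  std::vector<double> oob_sum(n, 0.0);
  std::vector<int> oob_cnt(n, 0);
  for (int t = 0; t < n_trees; ++t)
    for (int i : tree_oob[t]) {
      oob_sum[i] += predict_tree(forest, forest.root[t], X.data(), n, i,
                                 nullptr, -1);
      oob_cnt[i]++;
    }
  for (int i = 0; i < n; ++i)
    if (oob_cnt[i] > 0) oob_pred[i] = oob_sum[i] / oob_cnt[i];

  // baseline per-tree OOB MSE
  std::vector<double> mse0(n_trees, 0.0);
  for (int t = 0; t < n_trees; ++t) {
    if (tree_oob[t].empty()) continue;
    double s = 0.0;
    for (int i : tree_oob[t]) {
      double e = predict_tree(forest, forest.root[t], X.data(), n, i,
                              nullptr, -1) - y[i];
      s += e * e;
    }
    mse0[t] = s / tree_oob[t].size();
  }

  // conditional permutation importance: one shared permutation of each
  // variable, drawn within its observation groups, applied to all trees
  NumericVector importance(p, 0.0);
  std::vector<double> xperm(n);
  for (int v = 0; v < p; ++v) {
    const double* xv = &X[(size_t)v * n];
    for (int i = 0; i < n; ++i) xperm[i] = xv[i];
    // group indices and shuffle values within each group
    std::vector<std::pair<int, int>> gi(n);
    for (int i = 0; i < n; ++i) gi[i] = {obs_group(i, v), i};
    std::stable_sort(gi.begin(), gi.end(),
                     [](const std::pair<int, int>& a, const std::pair<int, int>& b) {
                       return a.first < b.first;
                     });
    size_t a = 0;
    while (a < gi.size()) {
      size_t bnd = a;
      while (bnd < gi.size() && gi[bnd].first == gi[a].first) ++bnd;
      for (size_t k = bnd - 1; k > a; --k) {
        size_t j = a + rand_int((int)(k - a + 1));
        std::swap(xperm[gi[k].second], xperm[gi[j].second]);
      }
      a = bnd;
    }
    double inc = 0.0;
    int used_trees = 0;
    for (int t = 0; t < n_trees; ++t) {
      if (tree_oob[t].empty()) continue;
      double s = 0.0;
      for (int i : tree_oob[t]) {
        double e = predict_tree(forest, forest.root[t], X.data(), n, i,
                                xperm.data(), v) - y[i];
        s += e * e;
      }
      inc += s / tree_oob[t].size() - mse0[t];
      used_trees++;
    }
    importance[v] = used_trees ? inc / used_trees : 0.0;
  }

  int nsp = (int)splits.size() / 3;
  NumericMatrix sm(nsp, 3);
  NumericVector impurity(p, 0.0);
  for (int k = 0; k < nsp; ++k) {
    sm(k, 0) = splits[3 * k] + 1;  // 1-based for R
    sm(k, 1) = splits[3 * k + 1];
    sm(k, 2) = splits[3 * k + 2];
    impurity[(int)splits[3 * k]] += splits[3 * k + 2];
  }

  return List::create(Named("oob_pred") = oob_pred,
                      Named("importance") = importance,
                      Named("impurity") = impurity,
                      Named("splits") = sm);
}
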