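// CART regression trees, bagged ensembles and exact interventional Shapley
// attribution. Trees are stored as parallel arrays (feature < 0 marks a
// leaf). All randomness comes from R's RNG so set.seed() on the R side
// makes every grow deterministic.

#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>

using namespace Rcpp;

namespace {

struct TreeBuf {
  std::vector<int> feature;   // split feature (0-based), -1 for leaf
  std::vector<double> thr;    // split threshold (go left if x <= thr)
  std::vector<int> left, right;
  std::vector<double> value;  // node mean of y
};

struct GrowParams {
  int mtry;
  int min_split;   // do not split nodes with fewer samples than this
  int min_leaf;    // minimum samples on each side of a split
  int max_depth;   // <= 0 means unlimited
  double stop_frac; // stop when node variance <= stop_frac * root variance
};

// sample `k` of 0..(p-1) without replacement using R's RNG
static void sample_features(int p, int k, std::vector<int> &out) {
  out.resize(p);
  for (int i = 0; i < p; ++i) out[i] = i;
  if (k >= p) return;
  for (int i = 0; i < k; ++i) {
    int j = i + (int)std::floor(unif_rand() * (p - i));
    if (j >= p) j = p - 1;
    std::swap(out[i], out[j]);
  }
  out.resize(k);
  std::sort(out.begin(), out.end()); // deterministic split scan order
}

static int grow_node(const NumericMatrix &X, const NumericVector &y,
                     std::vector<int> &rows, int lo, int hi, int depth,
                     double root_var, const GrowParams &par, TreeBuf &tb) {
  const int n = hi - lo;
  double sum = 0.0, ss = 0.0;
  for (int i = lo; i < hi; ++i) sum += y[rows[i]];
  const double mean = sum / n;
  for (int i = lo; i < hi; ++i) {
    const double d = y[rows[i]] - mean;
    ss += d * d;
  }
  const int node = (int)tb.feature.size();
  tb.feature.push_back(-1);
  tb.thr.push_back(0.0);
  tb.left.push_back(-1);
  tb.right.push_back(-1);
  tb.value.push_back(mean);

  const double node_var = ss / n;
  bool stop = n < par.min_split || n < 2 * par.min_leaf || ss <= 0.0;
  if (!stop && par.max_depth > 0 && depth >= par.max_depth) stop = true;
  if (!stop && par.stop_frac > 0.0 && node_var <= par.stop_frac * root_var)
    stop = true;
  if (stop) return node;

  std::vector<int> feats;
  sample_features(X.ncol(), par.mtry, feats);

  int best_f = -1;
  double best_gain = 0.0, best_thr = 0.0;
  std::vector<std::pair<double, double> > vals(n); // (x, y)
  for (size_t fi = 0; fi < feats.size(); ++fi) {
    const int f = feats[fi];
    for (int i = 0; i < n; ++i) {
      const int r = rows[lo + i];
      vals[i] = std::make_pair(X(r, f), y[r]);
    }
    std::sort(vals.begin(), vals.end());
    double lsum = 0.0;
    for (int i = 0; i < n - 1; ++i) {
      lsum += vals[i].second;
      if (vals[i + 1].first <= vals[i].first) continue; // tied x, no cut here
      const int nl = i + 1, nr = n - nl;
      if (nl < par.min_leaf || nr < par.min_leaf) continue;
      const double rsum = sum - lsum;
      const double gain =
          lsum * lsum / nl + rsum * rsum / nr - sum * sum / n;
      if (gain > best_gain + 1e-12) {
        best_gain = gain;
        best_f = f;
        best_thr = 0.5 * (vals[i].first + vals[i + 1].first);
      }
    }
  }
  if (best_f < 0) return node;

  // partition rows in place: x <= thr to the front
  int mid = lo;
  for (int i = lo; i < hi; ++i)
    if (X(rows[i], best_f) <= best_thr) std::swap(rows[mid++], rows[i]);
  if (mid == lo || mid == hi) return node; // numerical safety

  tb.feature[node] = best_f;
  tb.thr[node] = best_thr;
  tb.left[node] = grow_node(X, y, rows, lo, mid, depth + 1, root_var, par, tb);
  tb.right[node] = grow_node(X, y, rows, mid, hi, depth + 1, root_var, par, tb);
  return node;
}

static List tree_to_list(const TreeBuf &tb) {
  return List::create(_["feature"] = wrap(tb.feature), _["thr"] = wrap(tb.thr),
                      _["left"] = wrap(tb.left), _["right"] = wrap(tb.right),
                      _["value"] = wrap(tb.value));
}

static double predict_row(const IntegerVector &feature,
                          const NumericVector &thr, const IntegerVector &left,
                          const IntegerVector &right, const NumericVector &value,
                          const NumericMatrix &X, int r) {
  int node = 0;
  while (feature[node] >= 0)
    node = (X(r, feature[node]) <= thr[node]) ? left[node] : right[node];
  return value[node];
}

// Exact Shapley for the pair game defined by explicand x and background z:
// walk the tree; when x and z diverge on an unassigned feature, branch and
// record the side. At a leaf with a x-side and b z-side features on the
// path the leaf value contributes v*(a-1)!b!/(a+b)! to each x-side feature
// and -v*a!(b-1)!/(a+b)! to each z-side feature.
struct ShapCtx {
  const IntegerVector *feature;
  const NumericVector *thr;
  const IntegerVector *left, *right;
  const NumericVector *value;
  const NumericMatrix *X;
  const NumericMatrix *Z;
  int xi, zi;
  std::vector<int> side;        // 0 unassigned, 1 x-side, 2 z-side
  std::vector<int> path;        // assigned features in path order
  double *phi;                  // length p accumulator
  double w;                     // outer weight (1/(ntree*nbg))
  const std::vector<double> *lfact;
};

static void shap_recurse(ShapCtx &c, int node) {
  const int f = (*c.feature)[node];
  if (f < 0) {
    int a = 0, b = 0;
    for (size_t i = 0; i < c.path.size(); ++i)
      (c.side[c.path[i]] == 1) ? ++a : ++b;
    if (a + b == 0) return; // reached for every coalition: no attribution
    const double v = (*c.value)[node];
    const std::vector<double> &lf = *c.lfact;
    if (a > 0) {
      const double wA = v * std::exp(lf[a - 1] + lf[b] - lf[a + b]);
      for (size_t i = 0; i < c.path.size(); ++i)
        if (c.side[c.path[i]] == 1) c.phi[c.path[i]] += c.w * wA;
    }
    if (b > 0) {
      const double wB = v * std::exp(lf[a] + lf[b - 1] - lf[a + b]);
      for (size_t i = 0; i < c.path.size(); ++i)
        if (c.side[c.path[i]] == 2) c.phi[c.path[i]] -= c.w * wB;
    }
    return;
  }
  const double t = (*c.thr)[node];
  const int dx = ((*c.X)(c.xi, f) <= t) ? (*c.left)[node] : (*c.right)[node];
  const int dz = ((*c.Z)(c.zi, f) <= t) ? (*c.left)[node] : (*c.right)[node];
  if (c.side[f] == 1) {
    shap_recurse(c, dx);
  } else if (c.side[f] == 2) {
    shap_recurse(c, dz);
  } else if (dx == dz) {
    shap_recurse(c, dx);
  } else {
    c.side[f] = 1;
    c.path.push_back(f);
    shap_recurse(c, dx);
    c.side[f] = 2;
    shap_recurse(c, dz);
    c.path.pop_back();
    c.side[f] = 0;
  }
}

} // namespace

//' @noRd
// [[Rcpp::export(name = ".cpp_grow_trees")]]
List cpp_grow_trees(NumericMatrix X, NumericVector y, int ntree, int mtry,
                    int min_split, int min_leaf, int max_depth,
                    double stop_frac, bool bootstrap) {
  const int n = X.nrow();
  if (y.size() != n) stop("length(y) must match nrow(X)");
  if (n < 1) stop("no samples");
  RNGScope scope;
  List out(ntree);
  std::vector<int> rows(n);
  for (int t = 0; t < ntree; ++t) {
    if (bootstrap) {
      for (int i = 0; i < n; ++i) {
        int j = (int)std::floor(unif_rand() * n);
        if (j >= n) j = n - 1;
        rows[i] = j;
      }
    } else {
      for (int i = 0; i < n; ++i) rows[i] = i;
    }
    double sum = 0.0, ss = 0.0;
    for (int i = 0; i < n; ++i) sum += y[rows[i]];
    const double mean = sum / n;
    for (int i = 0; i < n; ++i) {
      const double d = y[rows[i]] - mean;
      ss += d * d;
    }
    GrowParams par;
    par.mtry = (mtry < 1) ? X.ncol() : std::min(mtry, (int)X.ncol());
    par.min_split = std::max(min_split, 2);
    par.min_leaf = std::max(min_leaf, 1);
    par.max_depth = max_depth;
    par.stop_frac = stop_frac;
    TreeBuf tb;
    grow_node(X, y, rows, 0, n, 0, ss / n, par, tb);
    out[t] = tree_to_list(tb);
  }
  return out;
}

//' @noRd
// [[Rcpp::export(name = ".cpp_predict_trees")]]
NumericMatrix cpp_predict_trees(List trees, NumericMatrix X) {
  const int n = X.nrow(), T = trees.size();
  NumericMatrix out(n, T);
  for (int t = 0; t < T; ++t) {
    List tr = trees[t];
    IntegerVector feature = tr["feature"], left = tr["left"], right = tr["right"];
    NumericVector thr = tr["thr"], value = tr["value"];
    for (int i = 0; i < n; ++i)
      out(i, t) = predict_row(feature, thr, left, right, value, X, i);
  }
  return out;
}

//' @noRd
// [[Rcpp::export(name = ".cpp_predict_forest")]]
NumericVector cpp_predict_forest(List trees, NumericMatrix X) {
  const int n = X.nrow(), T = trees.size();
  NumericVector out(n);
  for (int t = 0; t < T; ++t) {
    List tr = trees[t];
    IntegerVector feature = tr["feature"], left = tr["left"], right = tr["right"];
    NumericVector thr = tr["thr"], value = tr["value"];
    for (int i = 0; i < n; ++i)
      out[i] += predict_row(feature, thr, left, right, value, X, i);
  }
  for (int i = 0; i < n; ++i) out[i] /= T;
  return out;
}

//' @noRd
// [[Rcpp::export(name = ".cpp_perm_importance")]]
NumericMatrix cpp_perm_importance(List trees, NumericMatrix X, NumericVector y,
                                  int nperm) {
  const int n = X.nrow(), p = X.ncol(), T = trees.size();
  RNGScope scope;
  // flatten trees once
  std::vector<IntegerVector> fs, ls, rs;
  std::vector<NumericVector> ts, vs;
  for (int t = 0; t < T; ++t) {
    List tr = trees[t];
    fs.push_back(tr["feature"]); ls.push_back(tr["left"]);
    rs.push_back(tr["right"]); ts.push_back(tr["thr"]); vs.push_back(tr["value"]);
  }
  NumericMatrix Xp(clone(X));
  std::vector<double> pred(n);
  double base = 0.0;
  for (int i = 0; i < n; ++i) {
    double s = 0.0;
    for (int t = 0; t < T; ++t)
      s += predict_row(fs[t], ts[t], ls[t], rs[t], vs[t], Xp, i);
    pred[i] = s / T;
    const double d = pred[i] - y[i];
    base += d * d;
  }
  base = std::sqrt(base / n);
  NumericMatrix out(2, p); // row 0: mean delta RMSE, row 1: sd
  std::vector<double> col(n);
  for (int j = 0; j < p; ++j) {
    bool constant = true;
    for (int i = 1; i < n && constant; ++i)
      if (X(i, j) != X(0, j)) constant = false;
    if (constant) { out(0, j) = 0.0; out(1, j) = 0.0; continue; }
    double sum = 0.0, sumsq = 0.0;
    for (int r = 0; r < nperm; ++r) {
      for (int i = 0; i < n; ++i) col[i] = X(i, j);
      for (int i = n - 1; i > 0; --i) { // Fisher-Yates off R's RNG
        int k = (int)std::floor(unif_rand() * (i + 1));
        if (k > i) k = i;
        std::swap(col[i], col[k]);
      }
      for (int i = 0; i < n; ++i) Xp(i, j) = col[i];
      double sse = 0.0;
      for (int i = 0; i < n; ++i) {
        double s = 0.0;
        for (int t = 0; t < T; ++t)
          s += predict_row(fs[t], ts[t], ls[t], rs[t], vs[t], Xp, i);
        const double d = s / T - y[i];
        sse += d * d;
      }
      const double delta = std::sqrt(sse / n) - base;
      sum += delta; sumsq += delta * delta;
    }
    for (int i = 0; i < n; ++i) Xp(i, j) = X(i, j);
    out(0, j) = sum / nperm;
    out(1, j) = (nperm > 1)
        ? std::sqrt(std::max(0.0, (sumsq - sum * sum / nperm) / (nperm - 1)))
        : 0.0;
  }
  return out;
}

//' @noRd
// [[Rcpp::export(name = ".cpp_shap_trees")]]
NumericMatrix cpp_shap_trees(List trees, NumericMatrix X, NumericMatrix Z) {
  const int n = X.nrow(), p = X.ncol(), T = trees.size(), nz = Z.nrow();
  if (Z.ncol() != p) stop("background must have the same number of features");
  // log-factorials up to the deepest possible path
  std::vector<double> lfact(1, 0.0);
  for (int k = 1; k <= 4096; ++k)
    lfact.push_back(lfact[k - 1] + std::log((double)k));
  NumericMatrix phi(n, p);
  std::vector<double> acc(p);
  for (int t = 0; t < T; ++t) {
    List tr = trees[t];
    IntegerVector feature = tr["feature"], left = tr["left"], right = tr["right"];
    NumericVector thr = tr["thr"], value = tr["value"];
    ShapCtx c;
    c.feature = &feature;
    c.thr = &thr;
    c.left = &left;
    c.right = &right;
    c.value = &value;
    c.X = &X;
    c.Z = &Z;
    c.side.assign(p, 0);
    c.lfact = &lfact;
    c.w = 1.0 / ((double)T * (double)nz);
    for (int i = 0; i < n; ++i) {
      std::fill(acc.begin(), acc.end(), 0.0);
      c.phi = acc.data();
      c.xi = i;
      for (int z = 0; z < nz; ++z) {
        c.zi = z;
        shap_recurse(c, 0);
      }
      for (int j = 0; j < p; ++j) phi(i, j) += acc[j];
    }
  }
  return phi;
}
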