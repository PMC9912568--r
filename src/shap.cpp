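#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Tree routing: x[feature] <= threshold goes left; feature < 0 marks a leaf.
static inline int route_leaf(const int* feature, const double* threshold,
                             const int* left, const int* right,
                             const double* x, int node) {
  while (feature[node] >= 0)
    node = (x[feature[node]] <= threshold[node]) ? left[node] : right[node];
  return node;
}

// [[Rcpp::export]]
NumericVector ms_predict(IntegerVector feature, NumericVector threshold,
                         IntegerVector left, IntegerVector right,
                         NumericVector value, IntegerVector offset,
                         NumericMatrix X) {
  const int T = offset.size(), m = X.nrow(), n = X.ncol();
  NumericVector out(m);
  std::vector<double> x(n);
  for (int i = 0; i < m; ++i) {
    for (int j = 0; j < n; ++j) x[j] = X(i, j);
    double s = 0.0;
    for (int t = 0; t < T; ++t) {
      const int off = offset[t];
      const int leaf = route_leaf(&feature[off], &threshold[off],
                                  &left[off], &right[off], x.data(), 0);
      s += value[off + leaf];
    }
    out[i] = s / T;
  }
  return out;
}

// Lazily filled tables of summed Shapley subset weights.
//
// For a root-to-leaf path whose feature set splits into `a` features that
// only the foreground sample x satisfies and `b` features that only the
// background row z satisfies (features both satisfy are unconstrained, a
// feature neither satisfies prunes the leaf), the Shapley sum over all
// coalitions collapses to closed forms:
//   feature in the a-set:  +leaf * P(a,b),  P = sum_k C(f,k) w(a-1+k)
//   feature in the b-set:  -leaf * N(a,b),  N = sum_k C(f,k) w(a+k)
// with f = n - a - b free features and w(s) = s! (n-s-1)! / n!.
struct WeightTables {
  int n;
  std::vector<double> logw, P, N;
  explicit WeightTables(int n_)
      : n(n_), logw(n_ > 0 ? n_ : 1),
        P((n_ + 1) * (n_ + 1), -1.0), N((n_ + 1) * (n_ + 1), -1.0) {
    for (int s = 0; s < n; ++s)
      logw[s] = R::lgammafn(s + 1.0) + R::lgammafn((double)(n - s)) -
                R::lgammafn(n + 1.0);
  }
  double getP(int a, int b) {  // requires a >= 1
    double& p = P[a * (n + 1) + b];
    if (p < 0) {
      const int f = n - a - b;
      double s = 0.0;
      for (int k = 0; k <= f; ++k)
        s += std::exp(R::lchoose((double)f, (double)k) + logw[a - 1 + k]);
      p = s;
    }
    return p;
  }
  double getN(int a, int b) {  // requires b >= 1
    double& q = N[a * (n + 1) + b];
    if (q < 0) {
      const int f = n - a - b;
      double s = 0.0;
      for (int k = 0; k <= f; ++k)
        s += std::exp(R::lchoose((double)f, (double)k) + logw[a + k]);
      q = s;
    }
    return q;
  }
};

// Per-(tree, background-row) exact interventional attribution. The walker
// tracks, for every feature touched on the current path, whether the
// foreground x and/or the background z satisfy all of its split conditions
// so far (state 1 = both, 2 = x only, 3 = z only); branches no hybrid
// vector can reach are pruned.
struct ShapWalker {
  const int *feature, *left, *right;
  const double *threshold, *value;
  const double *x, *z;
  std::vector<int>& state;  // per-feature, 0 = untouched
  std::vector<int>& path;   // features currently constrained
  double* phi;
  WeightTables& wt;
  int a = 0, b = 0;

  void leaf_contrib(double v) {
    for (size_t q = 0; q < path.size(); ++q) {
      const int j = path[q];
      if (state[j] == 2)      phi[j] += v * wt.getP(a, b);
      else if (state[j] == 3) phi[j] -= v * wt.getN(a, b);
    }
  }

  void descend(int f, bool xp, bool zp, int child) {
    const int old = state[f];
    const bool nx = (old == 0 || old == 1 || old == 2) && xp;
    const bool nz = (old == 0 || old == 1 || old == 3) && zp;
    if (!nx && !nz) return;  // unreachable under every coalition
    const int ns = nx ? (nz ? 1 : 2) : 3;
    if (old == 0) path.push_back(f);
    if (old == 2) --a; else if (old == 3) --b;
    if (ns == 2) ++a; else if (ns == 3) ++b;
    state[f] = ns;
    recurse(child);
    state[f] = old;
    if (ns == 2) --a; else if (ns == 3) --b;
    if (old == 2) ++a; else if (old == 3) ++b;
    if (old == 0) path.pop_back();
  }

  void recurse(int node) {
    const int f = feature[node];
    if (f < 0) {
      const double v = value[node];
      if (v != 0.0) leaf_contrib(v);
      return;
    }
    const bool xl = x[f] <= threshold[node], zl = z[f] <= threshold[node];
    descend(f, xl, zl, left[node]);
    descend(f, !xl, !zl, right[node]);
  }
};

// [[Rcpp::export]]
NumericMatrix ms_shap(IntegerVector feature, NumericVector threshold,
                      IntegerVector left, IntegerVector right,
                      NumericVector value, IntegerVector offset,
                      NumericMatrix X, NumericMatrix BG) {
  const int T = offset.size(), m = X.nrow(), n = X.ncol(), B = BG.nrow();
  WeightTables wt(n);
  NumericMatrix out(m, n);
  std::vector<int> state(n, 0);
  std::vector<int> path;
  std::vector<double> phi(n), xrow(n);
  std::vector<std::vector<double>> bg(B, std::vector<double>(n));
  for (int r = 0; r < B; ++r)
    for (int j = 0; j < n; ++j) bg[r][j] = BG(r, j);
  const double denom = (double)T * (double)B;

  for (int i = 0; i < m; ++i) {
    for (int j = 0; j < n; ++j) { xrow[j] = X(i, j); phi[j] = 0.0; }
    for (int t = 0; t < T; ++t) {
      const int off = offset[t];
      for (int r = 0; r < B; ++r) {
        ShapWalker w{&feature[off], &left[off], &right[off],
                     &threshold[off], &value[off],
                     xrow.data(), bg[r].data(), state, path, phi.data(), wt};
        w.recurse(0);
      }
      if ((t & 63) == 0) Rcpp::checkUserInterrupt();
    }
    for (int j = 0; j < n; ++j) out(i, j) = phi[j] / denom;
  }
  return out;
}
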