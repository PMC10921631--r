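#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Internal flattened forest representation (see R/forest.R):
//   feature[i]  split feature index (0-based) or -1 for a leaf
//   split[i]    threshold
//   yes/no[i]   global child node indices (-1 for leaves)
//   value[i]    leaf value (response margin contribution)
//   roots[t]    global index of tree t's root
//   leq         comparison convention: TRUE routes x <= split to `yes`
//               (ranger), FALSE routes x < split (xgboost)

static inline int descend_dir(double x, double split, bool leq) {
  return leq ? (x <= split ? 0 : 1) : (x < split ? 0 : 1);
}

// Shapley weight for a member of the "from-x" set A with |A| = a, |B| = b:
//   (a-1)! b! / (a+b)!   (and symmetrically for B members).
// Exact factorial table for small path sets, lgamma beyond.
static double shap_weight(int a, int b) {
  static const double fact[23] = {
    1.0, 1.0, 2.0, 6.0, 24.0, 120.0, 720.0, 5040.0, 40320.0, 362880.0,
    3628800.0, 39916800.0, 479001600.0, 6227020800.0, 87178291200.0,
    1307674368000.0, 20922789888000.0, 355687428096000.0,
    6402373705728000.0, 121645100408832000.0, 2432902008176640000.0,
    51090942171709440000.0, 1124000727777607680000.0};
  if (a + b <= 22) return fact[a - 1 >= 0 ? a - 1 : 0] * fact[b] / fact[a + b];
  return std::exp(std::lgamma((double)a) + std::lgamma((double)b + 1.0) -
                  std::lgamma((double)a + b + 1.0));
}

struct ShapWalker {
  const IntegerVector &feature, &yes, &no;
  const NumericVector &split, &value;
  bool leq;
  const double *x, *b;   // explicand and background rows (length p)
  std::vector<int> state;        // 0 unseen, 1 from-x, 2 from-b
  std::vector<int> alist, blist; // distinguishing features along path
  double *phi;                   // accumulator, length p
  double scale;                  // 1 / n_background

  ShapWalker(const IntegerVector &f, const NumericVector &s,
             const IntegerVector &y, const IntegerVector &n,
             const NumericVector &v, bool leq_, int p)
      : feature(f), yes(y), no(n), split(s), value(v), leq(leq_), x(NULL),
        b(NULL), state(p, 0), phi(NULL), scale(1.0) {}

  void leaf(double val) {
    int a = (int)alist.size(), bb = (int)blist.size();
    if (a + bb == 0) return; // reached under every coalition: no attribution
    if (a > 0) {
      double w = shap_weight(a, bb) * val * scale;
      for (int j : alist) phi[j] += w;
    }
    if (bb > 0) {
      double w = shap_weight(bb, a) * val * scale;
      for (int j : blist) phi[j] -= w;
    }
  }

  void walk(int node) {
    int f = feature[node];
    if (f < 0) { leaf(value[node]); return; }
    int dx = descend_dir(x[f], split[node], leq);
    int db = descend_dir(b[f], split[node], leq);
    int cx = dx == 0 ? yes[node] : no[node];
    int cb = db == 0 ? yes[node] : no[node];
    if (state[f] == 1) { walk(cx); return; }
    if (state[f] == 2) { walk(cb); return; }
    if (cx == cb) { walk(cx); return; }
    state[f] = 1; alist.push_back(f);
    walk(cx);
    alist.pop_back();
    state[f] = 2; blist.push_back(f);
    walk(cb);
    blist.pop_back(); state[f] = 0;
  }
};

// [[Rcpp::export]]
NumericVector forest_predict_cpp(NumericMatrix X, IntegerVector feature,
                                 NumericVector split, IntegerVector yes,
                                 IntegerVector no, NumericVector value,
                                 IntegerVector roots, bool leq) {
  int n = X.nrow(), T = roots.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    double acc = 0.0;
    for (int t = 0; t < T; ++t) {
      int node = roots[t];
      while (feature[node] >= 0) {
        int d = descend_dir(X(i, feature[node]), split[node], leq);
        node = d == 0 ? yes[node] : no[node];
      }
      acc += value[node];
    }
    out[i] = acc;
  }
  return out;
}

// Exact interventional Shapley attributions for a tree ensemble:
// for each explicand row of X, the Shapley values of the game
//   v(S) = mean over background rows r of f(r with columns S set to x)
// computed leaf-by-leaf per background row, then averaged. Efficiency
// (sum phi = f(x) - mean f(background)) holds to double precision.
// [[Rcpp::export]]
NumericMatrix treeshap_interventional_cpp(NumericMatrix X, NumericMatrix B,
                                          IntegerVector feature,
                                          NumericVector split,
                                          IntegerVector yes, IntegerVector no,
                                          NumericVector value,
                                          IntegerVector roots, bool leq) {
  int n = X.nrow(), m = B.nrow(), p = X.ncol(), T = roots.size();
  NumericMatrix phi(n, p);
  ShapWalker w(feature, split, yes, no, value, leq, p);
  w.scale = 1.0 / (double)m;
  std::vector<double> xrow(p), brow(p), acc(p);
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < p; ++j) xrow[j] = X(i, j);
    std::fill(acc.begin(), acc.end(), 0.0);
    w.x = xrow.data();
    w.phi = acc.data();
    for (int r = 0; r < m; ++r) {
      for (int j = 0; j < p; ++j) brow[j] = B(r, j);
      w.b = brow.data();
      for (int t = 0; t < T; ++t) w.walk(roots[t]);
    }
    for (int j = 0; j < p; ++j) phi(i, j) = acc[j];
    if (i % 64 == 0) Rcpp::checkUserInterrupt();
  }
  return phi;
}
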