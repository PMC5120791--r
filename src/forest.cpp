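#include <Rcpp.h>
#include <cstdint>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// splitmix64: deterministic across platforms, one independent stream per tree
struct Rng {
  uint64_t s;
  explicit Rng(uint64_t seed) : s(seed ^ 0x9E3779B97F4A7C15ULL) {}
  uint64_t next() {
    s += 0x9E3779B97F4A7C15ULL;
    uint64_t z = s;
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    return z ^ (z >> 31);
  }
  int below(int n) { return (int)(next() % (uint64_t)n); }
};

struct Split {
  int var;        // 0-based column, -1 = no admissible split
  bool is_cat;
  double thr;     // numeric: midpoint threshold, left = x <= thr
  uint32_t mask;  // categorical: bit (c-1) set = level code c goes left
  double gain;    // SSE reduction
  int n_left;
};

class TreeBuilder {
public:
  const double* X; const double* y; const int* nlev;
  int N, p, m, n_min;
  Rng rng;
  std::vector<int> idx, buf, pool, cand;
  std::vector<std::pair<double,double> > xy;
  // flattened tree: var < 0 marks a leaf, children are 0-based node ids
  std::vector<int> var_, left_, right_;
  std::vector<double> thr_, mask_, val_;

  TreeBuilder(const NumericMatrix& Xm, const NumericVector& yv,
              const IntegerVector& nl, int m_, int nmin_, uint64_t seed)
    : X(REAL(Xm)), y(REAL(yv)), nlev(INTEGER(nl)),
      N(Xm.nrow()), p(Xm.ncol()), m(m_), n_min(nmin_), rng(seed) {}

  double xval(int row, int col) const { return X[(size_t)col * N + row]; }

  // Exhaustive best split over the given (ascending) candidate columns.
  // Ties in gain keep the earliest candidate: schema order first, then
  // ascending threshold / ascending level mask.  Gains must exceed a
  // round-off guard so constant-response nodes never split.
  Split best_split(int lo, int hi, const std::vector<int>& vars) {
    int n = hi - lo;
    double S = 0.0, SS = 0.0;
    for (int i = lo; i < hi; ++i) { double yi = y[idx[i]]; S += yi; SS += yi * yi; }
    double base = S * S / n;
    double tol = 1e-12 * (SS + 1.0);
    Split best; best.var = -1; best.is_cat = false;
    best.thr = 0.0; best.mask = 0; best.gain = tol; best.n_left = 0;
    for (size_t k = 0; k < vars.size(); ++k) {
      int j = vars[k];
      if (nlev[j] == 0) {                       // numeric predictor
        xy.clear();
        for (int i = lo; i < hi; ++i)
          xy.push_back(std::make_pair(xval(idx[i], j), y[idx[i]]));
        std::sort(xy.begin(), xy.end());
        double sl = 0.0;
        for (int q = 0; q < n - 1; ++q) {
          sl += xy[q].second;
          if (xy[q].first == xy[q + 1].first) continue;
          int nl = q + 1, nr = n - nl;
          double sr = S - sl;
          double gain = sl * sl / nl + sr * sr / nr - base;
          if (gain > best.gain) {
            best.var = j; best.is_cat = false;
            best.thr = (xy[q].first + xy[q + 1].first) / 2.0;
            best.mask = 0; best.gain = gain; best.n_left = nl;
          }
        }
      } else {                                   // categorical predictor
        int L = nlev[j];
        double cs[32]; int cn[32];
        for (int c = 0; c < L; ++c) { cs[c] = 0.0; cn[c] = 0; }
        for (int i = lo; i < hi; ++i) {
          int c = (int)xval(idx[i], j) - 1;
          cn[c]++; cs[c] += y[idx[i]];
        }
        uint32_t full = (1u << L) - 1u;
        for (uint32_t msk = 1u; msk < full; ++msk) {
          if (!(msk & 1u)) continue;             // canonical: level 1 goes left
          int nl = 0; double sl = 0.0;
          for (int c = 0; c < L; ++c)
            if (msk & (1u << c)) { nl += cn[c]; sl += cs[c]; }
          if (nl == 0 || nl == n) continue;
          double sr = S - sl; int nr = n - nl;
          double gain = sl * sl / nl + sr * sr / nr - base;
          if (gain > best.gain) {
            best.var = j; best.is_cat = true;
            best.thr = 0.0; best.mask = msk; best.gain = gain; best.n_left = nl;
          }
        }
      }
    }
    return best;
  }

  // Draw m distinct columns (all p when m >= p, consuming no randomness),
  // returned ascending so tie-breaking is schema-ordered.
  void pick_vars() {
    cand.clear();
    if (m >= p) { for (int j = 0; j < p; ++j) cand.push_back(j); return; }
    pool.resize(p);
    for (int j = 0; j < p; ++j) pool[j] = j;
    for (int k = 0; k < m; ++k) {
      int r = k + rng.below(p - k);
      std::swap(pool[k], pool[r]);
      cand.push_back(pool[k]);
    }
    std::sort(cand.begin(), cand.end());
  }

  int build(int lo, int hi) {
    int n = hi - lo;
    int node = (int)var_.size();
    var_.push_back(-1); thr_.push_back(0.0); mask_.push_back(0.0);
    left_.push_back(-1); right_.push_back(-1); val_.push_back(0.0);
    Split s; s.var = -1;
    if (n >= n_min) {
      pick_vars();
      s = best_split(lo, hi, cand);
    }
    if (s.var < 0) {
      double S = 0.0;
      for (int i = lo; i < hi; ++i) S += y[idx[i]];
      val_[node] = S / n;
      return node;
    }
    buf.clear();
    int j = s.var;
    if (!s.is_cat) {
      for (int i = lo; i < hi; ++i) if (xval(idx[i], j) <= s.thr) buf.push_back(idx[i]);
      for (int i = lo; i < hi; ++i) if (!(xval(idx[i], j) <= s.thr)) buf.push_back(idx[i]);
    } else {
      for (int i = lo; i < hi; ++i) {
        int c = (int)xval(idx[i], j) - 1;
        if (s.mask & (1u << c)) buf.push_back(idx[i]);
      }
      for (int i = lo; i < hi; ++i) {
        int c = (int)xval(idx[i], j) - 1;
        if (!(s.mask & (1u << c))) buf.push_back(idx[i]);
      }
    }
    std::copy(buf.begin(), buf.end(), idx.begin() + lo);
    int mid = lo + s.n_left;
    var_[node] = j; thr_[node] = s.thr; mask_[node] = (double)s.mask;
    int lch = build(lo, mid);
    int rch = build(mid, hi);
    left_[node] = lch; right_[node] = rch;
    return node;
  }
};

static List tree_to_list(const TreeBuilder& tb, IntegerVector inbag) {
  return List::create(_["var"] = wrap(tb.var_), _["thr"] = wrap(tb.thr_),
                      _["mask"] = wrap(tb.mask_), _["left"] = wrap(tb.left_),
                      _["right"] = wrap(tb.right_), _["value"] = wrap(tb.val_),
                      _["inbag"] = inbag);
}

// rows: 1-based training row indices (may repeat for a bootstrap sample)
// [[Rcpp::export]]
List cpp_grow_tree(NumericMatrix X, NumericVector y, IntegerVector nlev,
                   int m, int n_min, double seed, IntegerVector rows) {
  TreeBuilder tb(X, y, nlev, m, n_min, (uint64_t)seed);
  int n = rows.size();
  tb.idx.resize(n);
  for (int i = 0; i < n; ++i) tb.idx[i] = rows[i] - 1;
  tb.build(0, n);
  return tree_to_list(tb, rows);
}

// [[Rcpp::export]]
List cpp_fit_forest(NumericMatrix X, NumericVector y, IntegerVector nlev,
                    int m, int n_min, NumericVector tree_seeds, bool bootstrap) {
  int T = tree_seeds.size(), N = X.nrow();
  List out(T);
  for (int t = 0; t < T; ++t) {
    TreeBuilder tb(X, y, nlev, m, n_min, (uint64_t)tree_seeds[t]);
    IntegerVector inbag(N);
    tb.idx.resize(N);
    if (bootstrap) {
      for (int i = 0; i < N; ++i) {
        int r = tb.rng.below(N);
        tb.idx[i] = r; inbag[i] = r + 1;
      }
    } else {
      for (int i = 0; i < N; ++i) { tb.idx[i] = i; inbag[i] = i + 1; }
    }
    tb.build(0, N);
    out[t] = tree_to_list(tb, inbag);
  }
  return out;
}

static double tree_pred_row(const int* var, const double* thr, const double* mask,
                            const int* left, const int* right, const double* value,
                            const int* nlev, const double* X, int N, int row) {
  int node = 0;
  while (var[node] >= 0) {
    int j = var[node];
    double xv = X[(size_t)j * N + row];
    bool goleft;
    if (nlev[j] == 0) goleft = (xv <= thr[node]);
    else {
      int c = (int)xv - 1;
      goleft = ((((uint32_t)mask[node]) >> c) & 1u) != 0;
    }
    node = goleft ? left[node] : right[node];
  }
  return value[node];
}

// [[Rcpp::export]]
NumericVector cpp_predict_tree(List tree, NumericMatrix X, IntegerVector nlev) {
  int n = X.nrow();
  IntegerVector var = tree["var"], left = tree["left"], right = tree["right"];
  NumericVector thr = tree["thr"], mask = tree["mask"], value = tree["value"];
  NumericVector out(n);
  for (int i = 0; i < n; ++i)
    out[i] = tree_pred_row(INTEGER(var), REAL(thr), REAL(mask), INTEGER(left),
                           INTEGER(right), REAL(value), INTEGER(nlev), REAL(X), n, i);
  return out;
}

// ensemble mean over trees (Eq-style tree averaging)
// [[Rcpp::export]]
NumericVector cpp_predict_forest(List trees, NumericMatrix X, IntegerVector nlev) {
  int T = trees.size(), n = X.nrow();
  NumericVector out(n);
  for (int t = 0; t < T; ++t) {
    List tr = trees[t];
    IntegerVector var = tr["var"], left = tr["left"], right = tr["right"];
    NumericVector thr = tr["thr"], mask = tr["mask"], value = tr["value"];
    for (int i = 0; i < n; ++i)
      out[i] += tree_pred_row(INTEGER(var), REAL(thr), REAL(mask), INTEGER(left),
                              INTEGER(right), REAL(value), INTEGER(nlev), REAL(X), n, i);
  }
  for (int i = 0; i < n; ++i) out[i] /= T;
  return out;
}

// vars: 1-based candidate columns; all rows of X are the node
// [[Rcpp::export]]
List cpp_best_split(NumericMatrix X, NumericVector y, IntegerVector nlev,
                    IntegerVector vars) {
  TreeBuilder tb(X, y, nlev, X.ncol(), 1, 0);
  int n = X.nrow();
  tb.idx.resize(n);
  for (int i = 0; i < n; ++i) tb.idx[i] = i;
  std::vector<int> vs(vars.begin(), vars.end());
  for (size_t i = 0; i < vs.size(); ++i) vs[i] -= 1;
  std::sort(vs.begin(), vs.end());
  Split s = tb.best_split(0, n, vs);
  return List::create(_["var"] = s.var + 1, _["is_cat"] = s.is_cat,
                      _["thr"] = s.thr, _["mask"] = (double)s.mask,
                      _["gain"] = (s.var < 0 ? 0.0 : s.gain),
                      _["n_left"] = s.n_left);
}
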