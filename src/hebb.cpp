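#include <Rcpp.h>
using namespace Rcpp;

// Normalized Hebbian update of the active rows of a weight matrix, in
// place: w' = (w + eta * y_i * P) / sum(w + eta * y_i * P), the sum over
// the row's support. Support is inferred from w > 0 (weights are strictly
// positive exactly on their support). Callers must own W exclusively
// (train_lissom deep-copies its fields on entry). Returns the Frobenius
// norm of the change. Two column-major passes keep the access pattern
// cache-friendly.
// [[Rcpp::export]]
double hebb_inplace(NumericMatrix W, IntegerVector act, NumericVector y,
                    NumericVector P, double eta) {
  const int m = act.size(), nc = W.ncol(), nr = W.nrow();
  if (m == 0 || eta == 0.0) return 0.0;
  std::vector<double> s(m, 0.0), yi(m);
  std::vector<int> rows(m);
  for (int k = 0; k < m; ++k) {
    rows[k] = act[k] - 1;
    yi[k] = eta * y[rows[k]];
  }
  double *w = REAL(W);
  for (int j = 0; j < nc; ++j) {
    const double pj = P[j];
    const double *col = w + (size_t)j * nr;
    if (pj != 0.0) {
      for (int k = 0; k < m; ++k) {
        const double wv = col[rows[k]];
        if (wv > 0.0) s[k] += wv + yi[k] * pj;
      }
    } else {
      for (int k = 0; k < m; ++k) s[k] += col[rows[k]];
    }
  }
  std::vector<double> inv(m);
  for (int k = 0; k < m; ++k) inv[k] = (s[k] > 0.0) ? 1.0 / s[k] : 1.0;
  double dnorm2 = 0.0;
  for (int j = 0; j < nc; ++j) {
    const double pj = P[j];
    double *col = w + (size_t)j * nr;
    for (int k = 0; k < m; ++k) {
      const double wv = col[rows[k]];
      if (wv > 0.0) {
        const double nw = (wv + yi[k] * pj) * inv[k];
        const double d = nw - wv;
        dnorm2 += d * d;
        col[rows[k]] = nw;
      }
    }
  }
  return std::sqrt(dnorm2);
}

// L[act, ] <- q * E[act, ] - r * I[act, ], in place (L owned by caller).
// [[Rcpp::export]]
void lateral_rows_inplace(NumericMatrix L, NumericMatrix E, NumericMatrix I,
                          IntegerVector act, double q, double r) {
  const int m = act.size(), nc = L.ncol(), nr = L.nrow();
  double *l = REAL(L);
  const double *e = REAL(E), *in = REAL(I);
  for (int j = 0; j < nc; ++j) {
    const size_t off = (size_t)j * nr;
    for (int k = 0; k < m; ++k) {
      const size_t ix = off + (act[k] - 1);
      l[ix] = q * e[ix] - r * in[ix];
    }
  }
}
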