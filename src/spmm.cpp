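#include <Rcpp.h>
using namespace Rcpp;

// C = A %*% B for a compressed-sparse-column A (dgCMatrix slots) and a
// dense B. The dense column is the outer loop so every pass touches
// contiguous columns of B and C.
// [[Rcpp::export]]
NumericMatrix spmm_cpp(IntegerVector Ap, IntegerVector Ai, NumericVector Ax,
                       int n_row, NumericMatrix B) {
  const int n_col_B = B.ncol();
  const int n_col_A = Ap.size() - 1;
  NumericMatrix C(n_row, n_col_B);
  const int *ap = Ap.begin(), *ai = Ai.begin();
  const double *ax = Ax.begin();
  for (int k = 0; k < n_col_B; ++k) {
    const double *b = &B(0, k);
    double *c = &C(0, k);
    for (int j = 0; j < n_col_A; ++j) {
      const double bj = b[j];
      if (bj == 0.0) continue;
      for (int idx = ap[j]; idx < ap[j + 1]; ++idx) c[ai[idx]] += ax[idx] * bj;
    }
  }
  return C;
}

// C = t(A) %*% B for the same storage (i.e. crossprod(A, B))
// [[Rcpp::export]]
NumericMatrix spmm_t_cpp(IntegerVector Ap, IntegerVector Ai,
                         NumericVector Ax, NumericMatrix B) {
  const int n_col_B = B.ncol();
  const int n_col_A = Ap.size() - 1;
  NumericMatrix C(n_col_A, n_col_B);
  const int *ap = Ap.begin(), *ai = Ai.begin();
  const double *ax = Ax.begin();
  for (int k = 0; k < n_col_B; ++k) {
    const double *b = &B(0, k);
    double *c = &C(0, k);
    for (int j = 0; j < n_col_A; ++j) {
      double acc = 0.0;
      for (int idx = ap[j]; idx < ap[j + 1]; ++idx) acc += ax[idx] * b[ai[idx]];
      c[j] += acc;
    }
  }
  return C;
}

// v += bias (row-broadcast) and optionally ReLU, in place on a freshly
// allocated matrix the caller owns
// [[Rcpp::export]]
void add_bias_relu_inplace(NumericMatrix v, NumericVector bias, bool relu) {
  const int n = v.nrow(), k = v.ncol();
  for (int c = 0; c < k; ++c) {
    double *col = &v(0, c);
    const double b = bias[c];
    if (relu) {
      for (int r = 0; r < n; ++r) {
        const double y = col[r] + b;
        col[r] = y > 0.0 ? y : 0.0;
      }
    } else {
      for (int r = 0; r < n; ++r) col[r] += b;
    }
  }
}

// g * (v > 0), the ReLU backward mask applied in one pass
// [[Rcpp::export]]
NumericMatrix relu_mask_mul(NumericMatrix g, NumericMatrix v) {
  const int n = g.nrow(), k = g.ncol();
  NumericMatrix out(n, k);
  for (int c = 0; c < k; ++c) {
    const double *gc = &g(0, c), *vc = &v(0, c);
    double *oc = &out(0, c);
    for (int r = 0; r < n; ++r) oc[r] = vc[r] > 0.0 ? gc[r] : 0.0;
  }
  return out;
}
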