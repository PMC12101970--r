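// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

// Fused three-layer graph convolution with mean pooling over frames:
//   H_k = relu(A (H_{k-1} W_k + b_k)),  H_0 = X,
//   pooled_t = mean over the vertices of frame t of H_3.
// The full operator is block-diagonal with one identical per-frame block A
// (symmetric-normalized adjacency with self-loops, compressed sparse
// columns). Everything runs in feature-major (transposed) layout so the
// sparse propagation is a contiguous d-wide AXPY per non-zero. The input
// X is data (never a tape node), so the backward pass returns weight/bias
// gradients only.

// Ct.col(i) += a * Bt.col(j) over the block-diagonal replication of A
static void spmm_t_layout(const IntegerVector &Ap, const IntegerVector &Ai,
                          const NumericVector &Ax, int V,
                          const arma::mat &Bt, arma::mat &Ct,
                          bool transpose_A) {
  const int n_blocks = Bt.n_cols / V;
  const int d = Bt.n_rows;
  for (int blk = 0; blk < n_blocks; ++blk) {
    const int off = blk * V;
    for (int j = 0; j < V; ++j) {
      for (int idx = Ap[j]; idx < Ap[j + 1]; ++idx) {
        const int i = Ai[idx];
        const double a = Ax[idx];
        // A column j holds rows i: forward uses C(i) += a B(j); the
        // transpose swaps the roles
        const double *b = Bt.colptr(off + (transpose_A ? i : j));
        double *c = Ct.colptr(off + (transpose_A ? j : i));
        for (int k = 0; k < d; ++k) c[k] += a * b[k];
      }
    }
  }
}

// one layer in transposed layout: relu(A (W^T Ht + b))
static arma::mat layer_fwd_t(const IntegerVector &Ap,
                             const IntegerVector &Ai,
                             const NumericVector &Ax, int V,
                             const arma::mat &Ht, const arma::mat &W,
                             const arma::vec &b) {
  arma::mat Pt = W.t() * Ht;      // (d_out x rows)
  Pt.each_col() += b;
  arma::mat Out(Pt.n_rows, Pt.n_cols, arma::fill::zeros);
  spmm_t_layout(Ap, Ai, Ax, V, Pt, Out, false);
  double *p = Out.memptr();
  const arma::uword ne = Out.n_elem;
  for (arma::uword i = 0; i < ne; ++i) {
    if (p[i] < 0.0) p[i] = 0.0;
  }
  return Out;
}

// [[Rcpp::export]]
List gcn3_pooled_forward(IntegerVector Ap, IntegerVector Ai,
                         NumericVector Ax, int V, const arma::mat &X,
                         const arma::mat &W1, const arma::vec &b1,
                         const arma::mat &W2, const arma::vec &b2,
                         const arma::mat &W3, const arma::vec &b3,
                         bool keep_hidden) {
  arma::mat Xt = X.t();
  arma::mat H1 = layer_fwd_t(Ap, Ai, Ax, V, Xt, W1, b1);
  arma::mat H2 = layer_fwd_t(Ap, Ai, Ax, V, H1, W2, b2);
  if (!keep_hidden) H1.reset();
  arma::mat H3 = layer_fwd_t(Ap, Ai, Ax, V, H2, W3, b3);
  const int n_blocks = H3.n_cols / V;
  arma::mat pooled(n_blocks, H3.n_rows);
  for (int blk = 0; blk < n_blocks; ++blk) {
    pooled.row(blk) =
      arma::sum(H3.cols(blk * V, (blk + 1) * V - 1), 1).t() / V;
  }
  if (!keep_hidden) return List::create(_["pooled"] = pooled);
  return List::create(_["pooled"] = pooled, _["H1"] = H1, _["H2"] = H2,
                      _["H3"] = H3);
}

// gradient of one transposed layer; fills gW (d_in x d_out) and gb;
// mutates gOut_t in place (relu mask)
static arma::mat layer_bwd_t(const IntegerVector &Ap,
                             const IntegerVector &Ai,
                             const NumericVector &Ax, int V,
                             const arma::mat &Hin_t,
                             const arma::mat &Hout_t, const arma::mat &W,
                             arma::mat &gOut_t, arma::mat &gW,
                             arma::rowvec &gb, bool need_input_grad) {
  double *g = gOut_t.memptr();
  const double *h = Hout_t.memptr();
  const arma::uword ne = gOut_t.n_elem;
  for (arma::uword i = 0; i < ne; ++i) {
    if (h[i] <= 0.0) g[i] = 0.0;
  }
  arma::mat gPt(gOut_t.n_rows, gOut_t.n_cols, arma::fill::zeros);
  spmm_t_layout(Ap, Ai, Ax, V, gOut_t, gPt, true);
  gW = Hin_t * gPt.t();            // (d_in x rows)(rows x d_out)
  gb = arma::sum(gPt, 1).t();
  if (need_input_grad) return W * gPt;
  return arma::mat();
}

// [[Rcpp::export]]
List gcn3_pooled_backward(IntegerVector Ap, IntegerVector Ai,
                          NumericVector Ax, int V, const arma::mat &X,
                          const arma::mat &W1, const arma::mat &W2,
                          const arma::mat &W3, const arma::mat &H1,
                          const arma::mat &H2, const arma::mat &H3,
                          const arma::mat &gPooled) {
  const int n_blocks = gPooled.n_rows;
  arma::mat gH3(H3.n_rows, H3.n_cols);
  for (int blk = 0; blk < n_blocks; ++blk) {
    arma::vec col = gPooled.row(blk).t() / V;
    gH3.cols(blk * V, (blk + 1) * V - 1).each_col() = col;
  }
  arma::mat gW1, gW2, gW3;
  arma::rowvec gb1, gb2, gb3;
  arma::mat gH2 = layer_bwd_t(Ap, Ai, Ax, V, H2, H3, W3, gH3, gW3, gb3,
                              true);
  arma::mat gH1 = layer_bwd_t(Ap, Ai, Ax, V, H1, H2, W2, gH2, gW2, gb2,
                              true);
  arma::mat Xt = X.t();
  layer_bwd_t(Ap, Ai, Ax, V, Xt, H1, W1, gH1, gW1, gb1, false);
  return List::create(
    _["gW1"] = gW1, _["gb1"] = NumericMatrix(1, gb1.n_elem, gb1.begin()),
    _["gW2"] = gW2, _["gb2"] = NumericMatrix(1, gb2.n_elem, gb2.begin()),
    _["gW3"] = gW3, _["gb3"] = NumericMatrix(1, gb3.n_elem, gb3.begin()));
}
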