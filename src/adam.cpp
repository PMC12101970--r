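#include <Rcpp.h>
using namespace Rcpp;

// One Adam update for a single parameter matrix, mutating the parameter and
// the first/second moment buffers in place (all owned by the optimizer
// state; nothing else aliases them across steps).
// [[Rcpp::export]]
void adam_update_inplace(NumericMatrix param, NumericMatrix grad,
                         NumericMatrix m, NumericMatrix v,
                         double lr, double beta1, double beta2,
                         double eps, double c1, double c2) {
  const R_xlen_t n = param.size();
  double *p = param.begin(), *g = grad.begin(), *mm = m.begin(),
         *vv = v.begin();
  for (R_xlen_t i = 0; i < n; ++i) {
    mm[i] = beta1 * mm[i] + (1.0 - beta1) * g[i];
    vv[i] = beta2 * vv[i] + (1.0 - beta2) * g[i] * g[i];
    p[i] -= lr * (mm[i] / c1) / (std::sqrt(vv[i] / c2) + eps);
  }
}
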