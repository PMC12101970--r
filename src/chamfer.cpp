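#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Nearest-neighbour search by a sorted sweep along the x axis: candidates
// are visited outward from the query's x rank and a direction is abandoned
// once its x gap alone exceeds the best squared distance found. Exact, and
// near-linear for surface-like point sets.
struct SweepIndex {
  std::vector<int> order;      // target indices sorted by x
  std::vector<double> xs;      // sorted x values
  const double *tx, *ty, *tz;  // column pointers of the target block
  int n;

  void build(const double *x, const double *y, const double *z, int n_) {
    n = n_;
    tx = x; ty = y; tz = z;
    order.resize(n);
    for (int i = 0; i < n; ++i) order[i] = i;
    std::sort(order.begin(), order.end(),
              [&](int a, int b) { return x[a] < x[b]; });
    xs.resize(n);
    for (int i = 0; i < n; ++i) xs[i] = x[order[i]];
  }

  // nearest target to (px, py, pz); writes squared distance to best2
  int query(double px, double py, double pz, double &best2) const {
    int pos = int(std::lower_bound(xs.begin(), xs.end(), px) - xs.begin());
    best2 = R_PosInf;
    int arg = 0;
    int lo = pos - 1, hi = pos;
    while (lo >= 0 || hi < n) {
      // advance on the side with the smaller x gap
      double dlo = (lo >= 0) ? px - xs[lo] : R_PosInf;
      double dhi = (hi < n) ? xs[hi] - px : R_PosInf;
      int j;
      if (dlo <= dhi) {
        if (dlo * dlo >= best2) { lo = -1; if (dhi * dhi >= best2) break; continue; }
        j = order[lo--];
      } else {
        if (dhi * dhi >= best2) { hi = n; if (dlo * dlo >= best2) break; continue; }
        j = order[hi++];
      }
      const double dx = px - tx[j], dy = py - ty[j], dz = pz - tz[j];
      const double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < best2) { best2 = d2; arg = j; }
    }
    return arg;
  }
};

// Chamfer distance, averaged over the T per-frame blocks of two stacked
// (T*V) x 3 coordinate matrices, together with its gradient with respect
// to the predicted coordinates (nearest-neighbour assignments held fixed,
// the usual subgradient). Used by the training loss; the user-facing
// metric functions are pure R.
// [[Rcpp::export]]
List chamfer_frames_cpp(NumericMatrix pred, NumericMatrix target, int V) {
  const int n = pred.nrow();
  const int T = n / V;
  NumericMatrix grad(n, 3);
  double total = 0.0;
  const double *px = &pred(0, 0), *py = &pred(0, 1), *pz = &pred(0, 2);
  const double *qx = &target(0, 0), *qy = &target(0, 1),
               *qz = &target(0, 2);
  SweepIndex it, ip;

  for (int f = 0; f < T; ++f) {
    const int off = f * V;
    it.build(qx + off, qy + off, qz + off, V);
    ip.build(px + off, py + off, pz + off, V);
    double ma = 0.0, mb = 0.0;
    // pred -> target direction
    for (int i = 0; i < V; ++i) {
      double d2;
      const int j = it.query(px[off + i], py[off + i], pz[off + i], d2);
      const double d = std::sqrt(d2);
      ma += d;
      const double w = 1.0 / (V * std::max(d, 1e-12));
      grad(off + i, 0) += (px[off + i] - qx[off + j]) * w;
      grad(off + i, 1) += (py[off + i] - qy[off + j]) * w;
      grad(off + i, 2) += (pz[off + i] - qz[off + j]) * w;
    }
    // target -> pred direction
    for (int j = 0; j < V; ++j) {
      double d2;
      const int i = ip.query(qx[off + j], qy[off + j], qz[off + j], d2);
      const double d = std::sqrt(d2);
      mb += d;
      const double w = 1.0 / (V * std::max(d, 1e-12));
      grad(off + i, 0) += (px[off + i] - qx[off + j]) * w;
      grad(off + i, 1) += (py[off + i] - qy[off + j]) * w;
      grad(off + i, 2) += (pz[off + i] - qz[off + j]) * w;
    }
    total += (ma + mb) / V;
  }
  return List::create(_["value"] = total / T, _["grad"] = grad);
}
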