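#include <Rcpp.h>
using namespace Rcpp;

// Composite-likelihood sweep scan inner loop.
//
// For every grid position and every alpha on the ladder, sums the
// precomputed per-site log-likelihood ratios log P_sweep(b | pe) -
// log P_background(b), where pe = 1 - exp(-alpha * d) is the escape
// probability at distance d, looked up in `L` (rows: a uniform grid of
// pe values in [0, 1]; columns: folded allele-count classes). The CLR
// at a grid point is the alpha-maximised sum floored at zero.
//
// [[Rcpp::export]]
NumericMatrix clr_scan_cpp(NumericVector site_pos, IntegerVector bidx,
                           NumericMatrix L, NumericVector grid_pos,
                           NumericVector alphas) {
  const int ns = site_pos.size(), ng = grid_pos.size(),
            na = alphas.size(), npe = L.nrow();
  NumericMatrix out(ng, 2);
  // Sites with alpha*d beyond `far` quantise to the last pe bin, whose
  // log ratio is identically zero (pe = 1 recovers the background
  // spectrum), so restricting each sum to |d| < far/alpha is exact.
  const double far = -std::log(0.5 / (npe - 1));
  const double *pos0 = &site_pos[0];
  for (int g = 0; g < ng; ++g) {
    double best = R_NegInf;
    int best_a = 0;
    const double x = grid_pos[g];
    for (int a = 0; a < na; ++a) {
      const double alpha = alphas[a];
      const double radius = far / alpha;
      const double *lo = std::lower_bound(pos0, pos0 + ns, x - radius);
      const double *hi = std::upper_bound(pos0, pos0 + ns, x + radius);
      double s = 0.0;
      for (const double *p = lo; p < hi; ++p) {
        const int i = p - pos0;
        const double d = std::fabs(*p - x);
        double pe = 1.0 - std::exp(-alpha * d);
        int r = (int)(pe * (npe - 1) + 0.5);
        if (r >= npe) r = npe - 1;
        s += L(r, bidx[i]);
      }
      if (s > best) { best = s; best_a = a; }
    }
    out(g, 0) = best > 0.0 ? best : 0.0;
    out(g, 1) = best_a + 1;  // 1-based index into the alpha ladder
  }
  return out;
}
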