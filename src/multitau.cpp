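#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Multi-tau correlation estimator with progressive binning and
// symmetric normalization: at every cascade level both series are
// coarsened by pairwise averaging; for each lag k the correlation is
//   G(k) = mean(a_i * b_{i+k}) / (mean_left(a) * mean_right(b)) - 1
// with the means taken over the overlapping windows at that level.
// Level 0 holds lags 1..m at base resolution; every further level adds
// lags m/2+1..m at twice the previous bin width.
// [[Rcpp::export]]
List multitau_cpp(NumericVector a, NumericVector b, int m) {
  if (m < 4 || m % 2 != 0) stop("m must be an even number >= 4");
  const R_xlen_t n0 = a.size();
  if (b.size() != n0) stop("channels must have equal length");
  if (n0 < 4 * m) stop("trace too short for one multi-tau cascade");

  std::vector<double> va(a.begin(), a.end()), vb(b.begin(), b.end());
  std::vector<double> lags, G;
  double res = 1.0;
  int level = 0;
  while (true) {
    const R_xlen_t n = (R_xlen_t)va.size();
    const int k_lo = (level == 0) ? 1 : m / 2 + 1;
    if (n < 2 * m) break;
    for (int k = k_lo; k <= m; ++k) {
      const R_xlen_t cnt = n - k;
      double sum = 0.0, sa = 0.0, sb = 0.0;
      for (R_xlen_t i = 0; i < cnt; ++i) {
        sum += va[i] * vb[i + k];
        sa += va[i];
        sb += vb[i + k];
      }
      const double ma = sa / cnt, mb = sb / cnt;
      if (ma <= 0.0 || mb <= 0.0)
        stop("zero-mean channel segment: correlation undefined");
      lags.push_back(k * res);
      G.push_back(sum / (cnt * ma * mb) - 1.0);
    }
    // coarsen by pairwise averaging
    const R_xlen_t nh = n / 2;
    for (R_xlen_t i = 0; i < nh; ++i) {
      va[i] = 0.5 * (va[2 * i] + va[2 * i + 1]);
      vb[i] = 0.5 * (vb[2 * i] + vb[2 * i + 1]);
    }
    va.resize(nh); vb.resize(nh);
    res *= 2.0;
    ++level;
  }
  return List::create(_["lag_bins"] = wrap(lags), _["G"] = wrap(G));
}
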