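#include <Rcpp.h>
using namespace Rcpp;

// False nearest neighbours (Kennel criterion) computed on forward windows
// (x_i, x_{i+tau}, ..., x_{i+(m-1)tau}); the candidate coordinate for the
// next dimension is x_{i+m*tau}.  Euclidean metric for the neighbour search,
// temporal (Theiler) exclusion of m*tau samples.
// Returns, per dimension m = 1..m_max, the false fraction and the number of
// neighbour pairs actually tested.
// [[Rcpp::export]]
List fnn_fractions_cpp(NumericVector x, int tau, int m_max,
                       double rtol, double atol) {
  const int N = x.size();
  const double sdx = sd(x);
  const double rd_floor = 1e-8 * sdx;  // numerically duplicate windows
  NumericVector frac(m_max), npairs(m_max);

  for (int m = 1; m <= m_max; ++m) {
    const int K = N - m * tau;  // windows whose added coordinate exists
    if (K < 2) { frac[m - 1] = NA_REAL; npairs[m - 1] = 0; continue; }
    const int theiler = m * tau;
    long nf = 0, np = 0;
    for (int i = 0; i < K; ++i) {
      double best = R_PosInf;
      int bj = -1;
      for (int j = 0; j < K; ++j) {
        int dtt = j - i; if (dtt < 0) dtt = -dtt;
        if (dtt <= theiler) continue;
        double d2 = 0.0;
        for (int k = 0; k < m; ++k) {
          double dd = x[i + k * tau] - x[j + k * tau];
          d2 += dd * dd;
          if (d2 >= best) break;
        }
        if (d2 < best && d2 > 0.0) { best = d2; bj = j; }
      }
      if (bj < 0) continue;
      double Rd = std::sqrt(best);
      double diff = std::fabs(x[i + m * tau] - x[bj + m * tau]);
      ++np;
      // windows identical to numerical precision are genuine neighbours;
      // the distance-ratio test on them is float noise
      if (Rd < rd_floor && diff < rd_floor) continue;
      if (diff / Rd > rtol || std::sqrt(best + diff * diff) / sdx > atol) ++nf;
    }
    frac[m - 1] = np > 0 ? (double)nf / np : NA_REAL;
    npairs[m - 1] = (double)np;
  }
  return List::create(_["fraction"] = frac, _["n_pairs"] = npairs);
}
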