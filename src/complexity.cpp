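#include <Rcpp.h>
using namespace Rcpp;

// Sample-entropy template-match counts.  B = pairs of length-m templates
// matching within r (Chebyshev), A = pairs of length-(m+1) templates,
// both over template starts i = 1..N-m, self-matches excluded.
// [[Rcpp::export]]
List sampen_counts_cpp(NumericVector x, int m, double r) {
  const int N = x.size();
  const int T = N - m;  // number of templates
  double A = 0.0, B = 0.0;
  for (int i = 0; i < T - 1; ++i) {
    for (int j = i + 1; j < T; ++j) {
      bool match = true;
      for (int k = 0; k < m; ++k) {
        if (std::fabs(x[i + k] - x[j + k]) > r) { match = false; break; }
      }
      if (!match) continue;
      B += 1.0;
      if (std::fabs(x[i + m] - x[j + m]) <= r) A += 1.0;
    }
  }
  return List::create(_["A"] = A, _["B"] = B);
}

// Kaspar-Schuster exhaustive-history parsing of a binary sequence;
// returns the production count c(n).  The final word, if non-exhaustive,
// still increments the count once.
// [[Rcpp::export]]
int lz_complexity_cpp(IntegerVector s) {
  const int n = s.size();
  if (n == 0) return 0;
  int c = 1, l = 1, i = 0, k = 1, kmax = 1;
  while (true) {
    if (s[i + k - 1] != s[l + k - 1]) {
      if (k > kmax) kmax = k;
      ++i;
      if (i == l) {
        ++c;
        l += kmax;
        if (l + 1 > n) break;
        i = 0; k = 1; kmax = 1;
      } else {
        k = 1;
      }
    } else {
      ++k;
      if (l + k > n) { ++c; break; }
    }
  }
  return c;
}
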