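// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

static inline double dist_rows(const NumericMatrix& E, int i, int j) {
  double d2 = 0.0;
  for (int k = 0; k < E.ncol(); ++k) {
    double dd = E(i, k) - E(j, k);
    d2 += dd * dd;
  }
  return std::sqrt(d2);
}

// Mean log-divergence curve of nearest-neighbour pairs (Rosenstein).
// For every reference point the nearest neighbour outside the Theiler
// window is tracked for up to max_steps; pairs are dropped once either
// trajectory leaves the data.  Returns the per-step sums of ln d and the
// number of surviving pairs so the mean (and its support) can be formed in R.
// [[Rcpp::export]]
List rosenstein_curve_cpp(NumericMatrix E, int theiler, int max_steps) {
  const int K = E.nrow(), m = E.ncol();
  std::vector<int> nn(K, -1);
  for (int i = 0; i < K; ++i) {
    double best = R_PosInf;
    int bj = -1;
    for (int j = 0; j < K; ++j) {
      int dtt = j - i; if (dtt < 0) dtt = -dtt;
      if (dtt <= theiler) continue;
      double d2 = 0.0;
      for (int k = 0; k < m; ++k) {
        double dd = E(i, k) - E(j, k);
        d2 += dd * dd;
        if (d2 >= best) break;
      }
      if (d2 < best && d2 > 0.0) { best = d2; bj = j; }
    }
    nn[i] = bj;
  }
  NumericVector sum_log(max_steps + 1), counts(max_steps + 1);
  int used = 0;
  for (int i = 0; i < K; ++i) {
    int j = nn[i];
    if (j < 0) continue;
    ++used;
    for (int s = 0; s <= max_steps; ++s) {
      if (i + s >= K || j + s >= K) break;
      double d = dist_rows(E, i + s, j + s);
      if (d > 0.0) { sum_log[s] += std::log(d); counts[s] += 1.0; }
    }
  }
  return List::create(_["sum_log"] = sum_log, _["counts"] = counts,
                      _["n_pairs"] = used);
}

// Wolf neighbour-replacement estimate of the largest Lyapunov exponent.
// Follows a fiducial trajectory; the companion point is evolved until the
// separation exceeds eps_max (or max_evolve steps), the log stretch is
// accumulated, and a replacement neighbour within eps_init that best
// preserves the separation direction is sought.  Angle constraint widened,
// then dropped, when no admissible candidate exists.
// [[Rcpp::export]]
List wolf_cpp(NumericMatrix E, double eps_init, double eps_max,
              double min_sep, int theiler, int max_evolve,
              double max_angle) {
  const int K = E.nrow(), m = E.ncol();
  int t = 0, nb = -1;
  double d0 = R_PosInf;

  // initial neighbour: nearest temporally separated point
  for (int j = 0; j < K - 1; ++j) {
    int dtt = j - t; if (dtt < 0) dtt = -dtt;
    if (dtt <= theiler) continue;
    double d = dist_rows(E, t, j);
    if (d > min_sep && d < d0) { d0 = d; nb = j; }
  }
  if (nb < 0)
    return List::create(_["sum_log"] = NA_REAL);

  double sum_log = 0.0;
  long sum_steps = 0;
  int M = 0, n_fallback = 0;
  double sum_T = 0.0;

  while (true) {
    // evolve the pair
    int steps = 0;
    double d = d0;
    while (steps < max_evolve && t + 1 < K && nb + 1 < K) {
      ++t; ++nb; ++steps;
      d = dist_rows(E, t, nb);
      if (d > eps_max) break;
    }
    if (steps == 0) break;
    sum_log += std::log(d / d0);
    sum_steps += steps;
    sum_T += steps;
    ++M;
    if (t >= K - 2) break;

    // replacement: candidate within eps_init minimising the angle to the
    // current separation vector
    int best = -1, nearest = -1;
    double best_ang = R_PosInf, best_d = R_PosInf, near_d = R_PosInf;
    for (int j = 0; j < K - 1; ++j) {
      int dtt = j - t; if (dtt < 0) dtt = -dtt;
      if (dtt <= theiler) continue;
      double dj = dist_rows(E, t, j);
      if (dj <= min_sep) continue;
      if (dj < near_d) { near_d = dj; nearest = j; }
      if (dj <= eps_init) {
        double dot = 0.0;
        for (int k = 0; k < m; ++k)
          dot += (E(nb, k) - E(t, k)) * (E(j, k) - E(t, k));
        double ang = std::acos(std::min(1.0, std::fabs(dot) / (d * dj)));
        if (ang < best_ang) { best_ang = ang; best = j; best_d = dj; }
      }
    }
    if (best >= 0) {
      if (best_ang > max_angle) ++n_fallback;
      nb = best; d0 = best_d;
    } else if (nearest >= 0) {
      ++n_fallback;
      nb = nearest; d0 = near_d;
    } else {
      break;
    }
  }
  return List::create(_["sum_log"] = sum_log,
                      _["sum_steps"] = (double)sum_steps,
                      _["n_segments"] = M,
                      _["mean_T"] = M > 0 ? sum_T / M : NA_REAL,
                      _["n_fallback"] = n_fallback);
}

// Sano-Sawada spectrum: local linear maps fitted by least squares over
// neighbourhoods, orthonormal basis propagated with QR (Gram-Schmidt)
// renormalisation at every fiducial step.
// [[Rcpp::export]]
List sano_cpp(NumericMatrix Em, int n_exp, double eps0, double eps_grow,
              int min_nb, int evolve, double ridge_scale) {
  const int K = Em.nrow(), m = Em.ncol();
  arma::mat E(Em.begin(), K, m, false);
  const int Kf = K - evolve;

  // attractor extent (max coordinate range) as the eps ceiling
  double extent = 0.0;
  for (int k = 0; k < m; ++k) {
    double mn = E.col(k).min(), mx = E.col(k).max();
    if (mx - mn > extent) extent = mx - mn;
  }

  arma::mat Q = arma::eye(m, m);
  Q = Q.cols(0, n_exp - 1);
  arma::vec lam(n_exp, arma::fill::zeros);
  long n_steps = 0, n_skipped = 0, n_fid = 0;
  std::vector<int> nb_idx;
  nb_idx.reserve(256);

  for (int jf = 0; jf + evolve < K; jf += evolve) {
    ++n_fid;
    double eps = eps0;
    nb_idx.clear();
    while (true) {
      nb_idx.clear();
      const double eps2 = eps * eps;
      for (int j = 0; j < Kf; ++j) {
        if (j == jf) continue;
        double d2 = 0.0;
        for (int k = 0; k < m; ++k) {
          double dd = E(j, k) - E(jf, k);
          d2 += dd * dd;
          if (d2 > eps2) break;
        }
        if (d2 <= eps2) nb_idx.push_back(j);
      }
      if ((int)nb_idx.size() >= min_nb || eps > extent) break;
      eps *= eps_grow;
    }
    const int n = nb_idx.size();
    if (n < min_nb) { ++n_skipped; continue; }

    arma::mat Y(m, n), Z(m, n);
    for (int c = 0; c < n; ++c) {
      int j = nb_idx[c];
      for (int k = 0; k < m; ++k) {
        Y(k, c) = E(j, k) - E(jf, k);
        Z(k, c) = E(j + evolve, k) - E(jf + evolve, k);
      }
    }
    arma::mat V = Y * Y.t() / n;         // eq. system  A V = C
    arma::mat C = Z * Y.t() / n;
    double ridge = ridge_scale * arma::trace(V) / m;
    V.diag() += ridge;
    arma::mat A;
    bool ok = arma::solve(A, V.t(), C.t(), arma::solve_opts::no_approx);
    if (!ok) { ++n_skipped; continue; }
    A = A.t();

    arma::mat Qn, Rr;
    if (!arma::qr_econ(Qn, Rr, A * Q)) { ++n_skipped; continue; }
    arma::vec dg = Rr.diag();
    if (arma::any(arma::abs(dg) < 1e-300)) { ++n_skipped; continue; }
    // keep diagonal positive for a proper orientation
    for (int c = 0; c < n_exp; ++c)
      if (dg[c] < 0) Qn.col(c) *= -1.0;
    lam += arma::log(arma::abs(dg));
    Q = Qn;
    ++n_steps;
  }
  return List::create(_["lambda_sums"] = NumericVector(lam.begin(), lam.end()),
                      _["n_steps"] = (double)n_steps,
                      _["n_skipped"] = (double)n_skipped,
                      _["n_fiducial"] = (double)n_fid);
}
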