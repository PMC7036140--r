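#' Delay selection by mutual information
#'
#' Estimates the mutual information \eqn{I(x_t; x_{t+\tau})} in bits for
#' candidate delays `1..tau_max` from a two-dimensional histogram with
#' equiprobable (quantile) bins, and selects the embedding delay.
#'
#' The selection rule favours the first *prominent* interior local
#' minimum of the MI curve that sits above a permutation-estimated bias
#' floor (mean + 3 SD of the MI of `n_shuffle` shuffled copies).  A
#' minimum counts as prominent when the curve later rises above it by at
#' least `prominence * I(1)`.  If `I(1)` is already at the floor the
#' series carries no serial dependence and `chosen_tau = 1`.  If the
#' curve decays monotonically into the floor (typical of strongly
#' chaotic maps and broadband noise) the fallback is the first delay at
#' which the autocorrelation magnitude drops below 1/e.
#'
#' @param series a [scalar_series()] (or anything [as_scalar_series()]
#'   accepts).
#' @param tau_max largest candidate delay; requires `N > 4 * tau_max`.
#' @param n_bins number of equiprobable bins per margin (>= 4).
#' @param n_shuffle permutations used for the bias floor.
#' @param prominence required rise after a local minimum, as a fraction
#'   of `I(1)`.
#' @return An `embedding_diagnostics` object: tibble of the MI curve
#'   plus `chosen_tau`, the bias floor and the rule that fired.
#' @export
mutual_information_delay <- function(series, tau_max = 40, n_bins = 16,
                                     n_shuffle = 20, prominence = 0.05) {
  series <- as_scalar_series(series)
  x <- series$values
  N <- length(x)
  check_scalar(tau_max, "tau_max", lower = 2, integer = TRUE)
  check_scalar(n_bins, "n_bins", lower = 4, integer = TRUE)
  if (N <= 4 * tau_max)
    abort(sprintf("series too short: need N > 4 * tau_max = %d", 4 * tau_max))
  if (sd(x) == 0) abort("zero-variance (constant) series")

  code <- quantile_codes(x, n_bins)
  mi <- vapply(seq_len(tau_max), function(tau)
    binned_mi(code[seq_len(N - tau)], code[(tau + 1):N], n_bins), 0)

  # permutation bias floor under an internal fixed-seed stream so that the
  # diagnostic is a deterministic function of its inputs
  shuffled <- with_seed(190716L, vapply(seq_len(n_shuffle), function(i) {
    cs <- sample(code)
    binned_mi(cs[seq_len(N - 1)], cs[2:N], n_bins)
  }, 0))
  floor_mi <- mean(shuffled) + 3 * sd(shuffled)

  chosen <- NULL; rule <- NULL
  if (mi[1] <= floor_mi) {
    chosen <- 1L; rule <- "at-floor"
  } else {
    prom <- prominence * mi[1]
    for (tau in 2:(tau_max - 1)) {
      # a genuine dip: below both flanking maxima by the prominence margin
      if (mi[tau] < mi[tau - 1] && mi[tau] <= mi[tau + 1] &&
          mi[tau] > floor_mi &&
          max(mi[1:tau]) - mi[tau] >= prom &&
          max(mi[tau:tau_max]) - mi[tau] >= prom) {
        chosen <- tau; rule <- "mi-minimum"
        break
      }
    }
    if (is.null(chosen)) {
      rho <- as.numeric(acf(x, lag.max = tau_max, plot = FALSE)$acf)[-1]
      idx <- which(abs(rho) < exp(-1))
      if (length(idx)) {
        chosen <- idx[1]; rule <- "acf-1/e"
      } else {
        chosen <- tau_max; rule <- "tau-max"
      }
    }
  }
  structure(
    list(mi_curve = tibble(tau = seq_len(tau_max), mi = mi),
         chosen_tau = as.integer(chosen), bias_floor = floor_mi,
         rule = rule, n_bins = as.integer(n_bins)),
    class = "embedding_diagnostics"
  )
}

quantile_codes <- function(x, n_bins) {
  brks <- unique(quantile(x, probs = seq(0, 1, length.out = n_bins + 1)))
  if (length(brks) < 3) abort("series has too few distinct values to bin")
  codes <- findInterval(x, brks[-c(1, length(brks))], left.open = TRUE) + 1L
  codes
}

binned_mi <- function(a, b, n_bins) {
  joint <- tabulate((a - 1L) * n_bins + b, nbins = n_bins * n_bins)
  joint <- joint / sum(joint)
  jm <- matrix(joint, n_bins, n_bins, byrow = TRUE)
  px <- rowSums(jm); py <- colSums(jm)
  nz <- jm > 0
  sum(jm[nz] * log2(jm[nz] / outer(px, py)[nz]))
}

#' Embedding dimension by false nearest neighbours
#'
#' Kennel-style criterion: for each dimension `m` the nearest neighbour
#' of every delay window (outside a Theiler window of `m * tau` samples)
#' is tested with the coordinate the next dimension would add; the
#' neighbour is *false* if that coordinate difference exceeds `rtol`
#' times the current distance, or if the grown distance exceeds `atol`
#' times the series SD.  `chosen_m` is the smallest dimension whose
#' false fraction falls below `fnn_threshold`; if none does, `m_max` is
#' returned with `converged = FALSE` (typical of stochastic signals).
#'
#' @param series input signal.
#' @param tau embedding delay in samples.
#' @param m_max largest dimension probed.
#' @param rtol,atol Kennel tolerances (defaults 10 and 2).
#' @param fnn_threshold acceptable false-neighbour fraction.
#' @return An `embedding_diagnostics` object with the FNN curve,
#'   `chosen_m` and the convergence flag.
#' @export
false_nearest_neighbors <- function(series, tau, m_max = 8, rtol = 10,
                                    atol = 2, fnn_threshold = 0.01) {
  series <- as_scalar_series(series)
  x <- series$values
  check_scalar(tau, "tau", lower = 1, integer = TRUE)
  check_scalar(m_max, "m_max", lower = 1, integer = TRUE)
  if (length(x) - m_max * tau < 2)
    abort("series too short to probe dimensions up to m_max at this tau")
  if (sd(x) == 0) abort("zero-variance (constant) series")
  res <- fnn_fractions_cpp(x, as.integer(tau), as.integer(m_max),
                           rtol, atol)
  frac <- res$fraction
  if (all(res$n_pairs == 0))
    abort("no neighbour pairs found outside the Theiler window")
  below <- which(is.finite(frac) & frac < fnn_threshold)
  converged <- length(below) > 0
  chosen_m <- if (converged) below[1] else m_max
  if (!converged)
    warn(sprintf(paste0("false-neighbour fraction never fell below %g ",
                        "(min %.3f); using m_max = %d"),
                 fnn_threshold, min(frac, na.rm = TRUE), m_max))
  structure(
    list(fnn_curve = tibble(m = seq_len(m_max), fraction = frac,
                            n_pairs = res$n_pairs),
         chosen_m = as.integer(chosen_m), converged = converged,
         rtol = rtol, atol = atol, fnn_threshold = fnn_threshold,
         tau = as.integer(tau)),
    class = "embedding_diagnostics"
  )
}

#' Delay-coordinate embedding
#'
#' Reconstructs an m-dimensional trajectory from a scalar series using
#' backward lags: row i is
#' \eqn{(x_i, x_{i-\tau}, \ldots, x_{i-(m-1)\tau})}, rows ordered by
#' time, giving `K = N - (m-1) tau` points.
#'
#' @param series input signal.
#' @param tau delay in samples.
#' @param m embedding dimension.
#' @return A `delay_embedding` with the `K x m` point matrix.
#' @examples
#' embed_delay(scalar_series(1:5), tau = 1, m = 2)$points
#' @export
embed_delay <- function(series, tau, m) {
  series <- as_scalar_series(series)
  x <- series$values
  N <- length(x)
  check_scalar(tau, "tau", lower = 1, integer = TRUE)
  check_scalar(m, "m", lower = 1, integer = TRUE)
  K <- N - (m - 1) * tau
  if (K < m + 1)
    abort(sprintf(
      "series too short to embed: need N >= %d for m = %d, tau = %d (have %d)",
      (m - 1) * tau + m + 1, m, tau, N))
  idx <- seq.int((m - 1) * tau + 1, N)
  points <- vapply(seq_len(m) - 1L, function(k) x[idx - k * tau],
                   numeric(K))
  points <- matrix(points, nrow = K, ncol = m)
  structure(
    list(points = points, tau = as.integer(tau), m = as.integer(m),
         source_length = N, sampling_interval = series$sampling_interval,
         label = series$label),
    class = "delay_embedding"
  )
}

#' @export
print.delay_embedding <- function(x, ...) {
  cat(sprintf("<delay_embedding> %d points, m = %d, tau = %d, dt = %g\n",
              nrow(x$points), x$m, x$tau, x$sampling_interval))
  invisible(x)
}

#' @export
print.embedding_diagnostics <- function(x, ...) {
  if (!is.null(x$chosen_tau))
    cat(sprintf("<embedding_diagnostics> chosen_tau = %d (%s), bias floor %.4f bits\n",
                x$chosen_tau, x$rule, x$bias_floor))
  if (!is.null(x$chosen_m))
    cat(sprintf("<embedding_diagnostics> chosen_m = %d (converged: %s)\n",
                x$chosen_m, x$converged))
  invisible(x)
}

#' Automatic embedding of a scalar series
#'
#' Convenience wrapper: delay from [mutual_information_delay()],
#' dimension from [false_nearest_neighbors()], then [embed_delay()].
#'
#' @param series input signal.
#' @param tau_max,n_bins passed to the MI stage.
#' @param m_max,rtol,atol,fnn_threshold passed to the FNN stage.
#' @param min_m optional floor on the dimension (e.g. when a 7-exponent
#'   spectrum is requested downstream).
#' @return A list with the `delay_embedding` and both diagnostics.
#' @export
select_embedding <- function(series, tau_max = 40, n_bins = 16, m_max = 8,
                             rtol = 10, atol = 2, fnn_threshold = 0.01,
                             min_m = 1) {
  series <- as_scalar_series(series)
  mi <- mutual_information_delay(series, tau_max = tau_max, n_bins = n_bins)
  tau <- mi$chosen_tau
  fnn <- false_nearest_neighbors(series, tau = tau, m_max = m_max,
                                 rtol = rtol, atol = atol,
                                 fnn_threshold = fnn_threshold)
  m <- max(fnn$chosen_m, min_m)
  list(embedding = embed_delay(series, tau = tau, m = m),
       tau = tau, m = m, mi = mi, fnn = fnn)
}
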