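#' Coarse-grain a series for multiscale entropy
#'
#' Averages non-overlapping windows of length `tau`; the j-th coarse
#' sample is the mean of window j, for `j = 1..floor(N / tau)`, trailing
#' remainder samples discarded.  Scale 1 returns the series unchanged.
#'
#' @param series input signal.
#' @param tau window length (scale), a positive integer `<= N`.
#' @return A `scalar_series` of length `floor(N / tau)` whose sampling
#'   interval is `tau` times the input's.
#' @examples
#' coarse_grain(scalar_series(c(1, 2, 3, 4)), 2)$values  # 1.5 3.5
#' @export
coarse_grain <- function(series, tau) {
  series <- as_scalar_series(series)
  check_scalar(tau, "tau", lower = 1, integer = TRUE)
  x <- series$values
  N <- length(x)
  if (tau > N) abort("tau exceeds the series length: coarse series is empty")
  if (tau == 1) return(series)
  J <- N %/% tau
  y <- colMeans(matrix(x[seq_len(J * tau)], nrow = tau))
  scalar_series(y, sampling_interval = series$sampling_interval * tau,
                label = series$label)
}

#' Sample entropy
#'
#' \eqn{S_E = \ln(B / A)} where B counts pairs of length-`m` templates
#' agreeing within the tolerance (Chebyshev distance) and A counts pairs
#' of length-`m+1` templates, self-matches excluded.  The tolerance is
#' `r` times the series SD (or `r` times `r_reference_sd` when the
#' tolerance must be anchored to another series, as in multiscale
#' entropy where all scales share the raw-series SD).
#'
#' With no template match at length `m+1` the entropy is `+Inf`,
#' returned as such (with the raw counts attached) rather than
#' substituted.
#'
#' @param series input signal (non-constant, `N > m + 1`).
#' @param m template length.
#' @param r tolerance in SD units.
#' @param r_reference_sd optional SD to scale `r` by instead of the
#'   series' own.
#' @return The entropy in nats, with attributes `A`, `B` (match counts)
#'   and `r_abs` (absolute tolerance used).
#' @export
sample_entropy <- function(series, m = 2, r = 0.2, r_reference_sd = NULL) {
  series <- as_scalar_series(series)
  x <- series$values
  check_scalar(m, "m", lower = 1, integer = TRUE)
  check_scalar(r, "r", lower = 0, open_lower = TRUE)
  if (length(x) <= m + 1)
    abort(sprintf("need more than m + 1 = %d samples", m + 1))
  s <- sd(x)
  if (s == 0) abort("zero-variance (constant) series")
  r_abs <- r * (r_reference_sd %||% s)
  cnt <- sampen_counts_cpp(x, as.integer(m), r_abs)
  value <- if (cnt$A == 0) {
    warn("no template match at length m + 1; sample entropy is +Inf")
    Inf
  } else if (cnt$B == 0) {
    warn("no template match at length m; sample entropy undefined, returning NaN")
    NaN
  } else {
    log(cnt$B / cnt$A)
  }
  structure(value, A = cnt$A, B = cnt$B, r_abs = r_abs)
}

#' Multiscale entropy profile
#'
#' Sample entropy of successively coarse-grained versions of the signal
#' ([coarse_grain()]), scales `1..d`.  The tolerance is fixed from the
#' raw series SD across all scales, so entropies are comparable between
#' scales.  The defaults (`m = 20`, `r = 0.4`, `d = 3`) are the EEG
#' parameter set used by the channel pipeline; note `m = 20` is far
#' above the customary 1-2 and relies on strong serial correlation for
#' matches to exist at all — short or near-white signals then legitimately
#' return `+Inf` at some scale.
#'
#' @param series input signal.
#' @param m template length.
#' @param r tolerance in units of the raw series SD.
#' @param d largest scale.
#' @return An `mse_profile` tibble `(scale, entropy, n_coarse, A, B)`
#'   with the parameters as attributes.
#' @export
multiscale_entropy <- function(series, m = 20, r = 0.4, d = 3) {
  series <- as_scalar_series(series)
  check_scalar(d, "d", lower = 1, integer = TRUE)
  sd_raw <- sd(series$values)
  if (sd_raw == 0) abort("zero-variance (constant) series")
  rows <- purrr::map(seq_len(d), function(scale) {
    coarse <- coarse_grain(series, scale)
    se <- withCallingHandlers(
      tryCatch(
        sample_entropy(coarse, m = m, r = r, r_reference_sd = sd_raw),
        error = function(e)
          abort(sprintf("multiscale entropy failed at scale %d: %s",
                        scale, conditionMessage(e)))
      ),
      warning = function(w) {
        warn(sprintf("scale %d: %s", scale, conditionMessage(w)))
        invokeRestart("muffleWarning")
      }
    )
    tibble(scale = scale, entropy = as.numeric(se),
           n_coarse = length(coarse$values),
           A = attr(se, "A"), B = attr(se, "B"))
  })
  out <- dplyr::bind_rows(rows)
  structure(out, class = c("mse_profile", class(out)),
            m = m, r = r, d = d, sd_raw = sd_raw)
}

#' Normalized Lempel-Ziv complexity
#'
#' The signal is binarized against its mean (`1` where the sample
#' exceeds the mean, ties and below mapped to `0`) and parsed with the
#' Kaspar-Schuster exhaustive-history rule into `c(n)` productions (the
#' final incomplete word counts once); the normalized complexity is
#' `c(n) / b(n)` with `b(n) = n / log2(n)`, which tends to 1 for a
#' fully random binary sequence.
#'
#' A 0/1-valued input passes through binarization unchanged, so
#' pre-binarized sequences can be fed directly.
#'
#' @param series input signal (`N >= 2`, non-constant).
#' @return An `lzc_result` with the binary summary, `c_n`, `b_n` and the
#'   normalized `lzc`.
#' @export
lempel_ziv_complexity <- function(series) {
  series <- as_scalar_series(series)
  x <- series$values
  if (sd(x) == 0) abort("zero-variance (constant) series")
  threshold <- mean(x)
  s <- as.integer(x > threshold)
  n <- length(s)
  c_n <- lz_complexity_cpp(s)
  b_n <- n / log2(n)
  structure(
    list(n = n, threshold = threshold,
         n_ones = sum(s), n_zeros = n - sum(s),
         c_n = c_n, b_n = b_n, lzc = c_n / b_n),
    class = "lzc_result"
  )
}

#' @export
print.lzc_result <- function(x, ...) {
  cat(sprintf("<lzc_result> n = %d (0s: %d, 1s: %d), c(n) = %d, LZC = %.4f\n",
              x$n, x$n_zeros, x$n_ones, x$c_n, x$lzc))
  invisible(x)
}
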