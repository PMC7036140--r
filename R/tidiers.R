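#' @export
tidy.lyapunov_spectrum <- function(x, ...) {
  tibble(index = seq_along(x$exponents), exponent = x$exponents,
         sign = strsplit(x$classification, "")[[1]])
}

#' @export
glance.lyapunov_spectrum <- function(x, ...) {
  tibble(n_exponents = length(x$exponents), lambda1 = x$exponents[1],
         ks_entropy = x$ks_entropy, classification = x$classification,
         zero_tol = x$zero_tol, method = x$method)
}

#' @export
tidy.lyapunov_estimate <- function(x, ...) {
  tibble(method = x$method, lambda1 = x$lambda1)
}

#' @export
glance.lyapunov_estimate <- function(x, ...) {
  d <- x$diagnostics
  tibble(method = x$method, lambda1 = x$lambda1,
         fit_r2 = d$fit_r2 %||% NA_real_,
         n_segments = d$n_segments %||% NA_integer_,
         low_confidence = d$low_confidence %||% !(d$reliable %||% TRUE))
}

#' @export
tidy.divergence_curve <- function(x, ...) {
  tibble::as_tibble(unclass(x))
}

#' @export
tidy.mse_profile <- function(x, ...) {
  tibble::as_tibble(unclass(x))
}

#' @export
tidy.lzc_result <- function(x, ...) {
  tibble(n = x$n, threshold = x$threshold, n_ones = x$n_ones,
         n_zeros = x$n_zeros, c_n = x$c_n, b_n = x$b_n, lzc = x$lzc)
}

#' @export
tidy.embedding_diagnostics <- function(x, ...) {
  if (!is.null(x$mi_curve)) x$mi_curve else x$fnn_curve
}

#' @export
tidy.trend_series <- function(x, ...) {
  tibble::as_tibble(unclass(x))
}

#' @export
tidy.channel_metrics <- function(x, ...) {
  tidyr::pivot_longer(tibble::as_tibble(unclass(x)),
                      -dplyr::any_of(c("channel", "tau", "dim_m")),
                      names_to = "metric", values_to = "value")
}
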