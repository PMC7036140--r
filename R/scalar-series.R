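#' Uniformly sampled scalar series
#'
#' The universal input of the toolkit: a univariate signal sampled at a
#' fixed interval.  Maps use `sampling_interval = 1` (one model iterate
#' per sample); flows and EEG use the integration step or `1/fs` so that
#' Lyapunov exponents come out in nats per unit time.
#'
#' @param values numeric vector of finite samples (degenerate
#'   single-sample series are allowed; estimators impose their own
#'   minimum lengths).
#' @param sampling_interval positive time step between samples.
#' @param label optional text label carried through results.
#' @return An object of class `scalar_series`.
#' @examples
#' s <- scalar_series(sin(seq(0, 10, by = 0.05)), sampling_interval = 0.05)
#' s
#' @export
scalar_series <- function(values, sampling_interval = 1, label = "") {
  values <- as.double(values)
  if (length(values) < 1) abort("a scalar series needs at least 1 sample")
  if (!all(is.finite(values))) abort("all series values must be finite")
  check_scalar(sampling_interval, "sampling_interval", lower = 0,
               open_lower = TRUE)
  structure(
    list(values = values, sampling_interval = as.double(sampling_interval),
         label = as.character(label)),
    class = "scalar_series"
  )
}

#' Coerce to a scalar series
#'
#' Accepts a numeric vector, a `ts`, a one-signal data frame (a `value`
#' column, or the single non-time column), or a `scalar_series`.
#'
#' @param x object to coerce.
#' @param ... passed to [scalar_series()].
#' @return A `scalar_series`.
#' @export
as_scalar_series <- function(x, ...) UseMethod("as_scalar_series")

#' @export
as_scalar_series.scalar_series <- function(x, ...) x

#' @export
as_scalar_series.numeric <- function(x, ...) scalar_series(x, ...)

#' @export
as_scalar_series.ts <- function(x, ...) {
  scalar_series(as.numeric(x), sampling_interval = 1 / stats::frequency(x), ...)
}

#' @export
as_scalar_series.data.frame <- function(x, ...) {
  nm <- tolower(names(x))
  value_col <- if ("value" %in% nm) which(nm == "value")[1] else {
    cand <- setdiff(seq_along(x), which(nm %in% c("time", "t")))
    if (length(cand) != 1)
      abort("data frame must have a `value` column or exactly one signal column")
    cand
  }
  args <- list(...)
  if (is.null(args$sampling_interval) && any(nm %in% c("time", "t"))) {
    tm <- x[[which(nm %in% c("time", "t"))[1]]]
    args$sampling_interval <- stats::median(diff(tm))
  }
  do.call(scalar_series, c(list(values = x[[value_col]]), args))
}

#' @export
print.scalar_series <- function(x, ...) {
  cat(sprintf("<scalar_series> %d samples, dt = %g%s\n",
              length(x$values), x$sampling_interval,
              if (nzchar(x$label)) paste0(", label: ", x$label) else ""))
  invisible(x)
}

#' @export
length.scalar_series <- function(x) length(x$values)

#' @export
as_tibble.scalar_series <- function(x, ...) {
  tibble(time = (seq_along(x$values) - 1) * x$sampling_interval,
         value = x$values)
}
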