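#' Specification of a classical benchmark system
#'
#' Describes one of the three reference systems used to validate the
#' Lyapunov estimators: the logistic map \eqn{x_{n+1} = R x_n (1 - x_n)},
#' the Henon map \eqn{x_{n+1} = 1 - a x_n^2 + y_n,\; y_{n+1} = b x_n},
#' or the Rossler flow
#' \eqn{\dot x = -y-z,\; \dot y = x + a y,\; \dot z = b + z(x - c)}.
#'
#' Defaults are the benchmark conditions used throughout the package:
#' `R = 4` (fully chaotic logistic map), `a = 1.4, b = 0.3` (Henon),
#' `a = b = 0.2, c = 5.7` (Rossler); 5000 retained samples after 1000
#' discarded transients for the maps, 10000 samples at `dt = 0.05` after
#' 500 time units of transient for the flow.  When `initial_state` is
#' omitted it is drawn (seeded) from a small region known to lie in the
#' basin of attraction.
#'
#' @param name one of `"logistic"`, `"henon"`, `"rossler"`.
#' @param params named list of map/flow parameters; defaults above.
#' @param initial_state numeric vector (length 1, 2 or 3 by system);
#'   `NULL` draws it using `seed`.
#' @param n_samples number of retained samples (>= 1).
#' @param transient samples discarded before output (>= 0).
#' @param dt integration step for the flow (ignored by maps).
#' @param seed integer seed for the random initial state.
#' @return A `system_spec` list.
#' @export
system_spec <- function(name = c("logistic", "henon", "rossler"),
                        params = NULL, initial_state = NULL,
                        n_samples = NULL, transient = NULL,
                        dt = 0.05, seed = NULL) {
  name <- match.arg(name)
  defaults <- switch(name,
    logistic = list(R = 4),
    henon    = list(a = 1.4, b = 0.3),
    rossler  = list(a = 0.2, b = 0.2, c = 5.7)
  )
  params <- modifyList(defaults, as.list(params %||% list()))
  missing_par <- setdiff(names(defaults), names(params))
  if (length(missing_par))
    abort(paste0("missing parameters for ", name, ": ",
                 paste(missing_par, collapse = ", ")))
  n_samples <- n_samples %||% if (name == "rossler") 10000L else 5000L
  transient <- transient %||% if (name == "rossler") 10000L else 1000L
  check_scalar(n_samples, "n_samples", lower = 1, integer = TRUE)
  check_scalar(transient, "transient", lower = 0, integer = TRUE)
  check_scalar(dt, "dt", lower = 0, open_lower = TRUE)
  dim_needed <- switch(name, logistic = 1L, henon = 2L, rossler = 3L)
  if (!is.null(initial_state)) {
    if (length(initial_state) != dim_needed || !all(is.finite(initial_state)))
      abort(sprintf("initial_state for %s must be %d finite values",
                    name, dim_needed))
    if (name == "logistic" &&
        (initial_state <= 0 || initial_state >= 1))
      abort("logistic initial state must lie in the open interval (0, 1)")
  }
  structure(
    list(name = name, params = params, initial_state = initial_state,
         n_samples = as.integer(n_samples), transient = as.integer(transient),
         dt = as.double(dt), seed = seed),
    class = "system_spec"
  )
}

draw_initial_state <- function(spec) {
  with_seed(spec$seed, switch(spec$name,
    logistic = runif(1, 0.01, 0.99),
    henon    = runif(2, c(0.0, 0.0), c(0.2, 0.2)),
    rossler  = 0.1 + runif(3, -0.05, 0.05)
  ))
}

#' Generate an orbit of a chaotic map
#'
#' Iterates the exact recurrence of the logistic or Henon map, discards
#' the transient, and returns the x coordinate as a [scalar_series()]
#' with `sampling_interval = 1` (one iterate per sample).
#'
#' @param spec a [system_spec()] with `name` `"logistic"` or `"henon"`.
#' @return A `scalar_series`.
#' @examples
#' orbit <- generate_map(system_spec("henon", n_samples = 1000, seed = 1))
#' @export
generate_map <- function(spec) {
  stopifnot(inherits(spec, "system_spec"))
  if (!spec$name %in% c("logistic", "henon"))
    abort("generate_map() handles the logistic and Henon maps; use generate_flow() for the Rossler system")
  state <- spec$initial_state %||% draw_initial_state(spec)
  n_total <- spec$transient + spec$n_samples
  out <- numeric(spec$n_samples)
  if (spec$name == "logistic") {
    R <- spec$params$R
    x <- state[1]
    for (i in seq_len(n_total)) {
      x <- R * x * (1 - x)
      if (!is.finite(x) || abs(x) > 1e6)
        abort(sprintf("logistic orbit diverged at iterate %d", i))
      if (i > spec$transient) out[i - spec$transient] <- x
    }
    if (any(out == 0))
      warn("logistic orbit hit the absorbing point x = 0; the remainder of the orbit is constant")
  } else {
    a <- spec$params$a; b <- spec$params$b
    x <- state[1]; y <- state[2]
    for (i in seq_len(n_total)) {
      xn <- 1 - a * x^2 + y
      yn <- b * x
      x <- xn; y <- yn
      if (!is.finite(x) || abs(x) > 1e6)
        abort(sprintf("Henon orbit diverged at iterate %d", i))
      if (i > spec$transient) out[i - spec$transient] <- x
    }
  }
  scalar_series(out, sampling_interval = 1, label = spec$name)
}

#' Generate a sampled trajectory of the Rossler flow
#'
#' Integrates the Rossler equations with a fixed-step 4th-order
#' Runge-Kutta scheme (via [deSolve::rk4()]), discards the transient,
#' and returns the x component sampled every `dt`.
#'
#' @param spec a [system_spec()] with `name = "rossler"`.
#' @param coords `"x"` (default) returns the scalar x series; `"all"`
#'   returns the full state matrix (columns x, y, z) for diagnostics.
#' @return A `scalar_series`, or a matrix when `coords = "all"`.
#' @export
generate_flow <- function(spec, coords = c("x", "all")) {
  stopifnot(inherits(spec, "system_spec"))
  coords <- match.arg(coords)
  if (spec$name != "rossler")
    abort("generate_flow() handles the Rossler system; use generate_map() for maps")
  state <- spec$initial_state %||% draw_initial_state(spec)
  names(state) <- c("x", "y", "z")
  p <- spec$params
  deriv <- function(t, s, parms) {
    list(c(-s[2] - s[3],
           s[1] + parms$a * s[2],
           parms$b + s[3] * (s[1] - parms$c)))
  }
  n_total <- spec$transient + spec$n_samples
  times <- seq(0, by = spec$dt, length.out = n_total)
  sol <- deSolve::rk4(y = state, times = times, func = deriv, parms = p)
  states <- unname(as.matrix(sol[, -1, drop = FALSE]))
  bad <- which(!is.finite(rowSums(states)))
  if (length(bad))
    abort(sprintf("Rossler integration blew up at t = %g", times[bad[1]]))
  keep <- states[(spec$transient + 1):n_total, , drop = FALSE]
  if (coords == "all") {
    colnames(keep) <- c("x", "y", "z")
    return(keep)
  }
  scalar_series(keep[, 1], sampling_interval = spec$dt, label = "rossler")
}
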