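new_lyapunov_estimate <- function(method, lambda1, params, diagnostics,
                                  sampling_interval) {
  structure(
    list(method = method, lambda1 = lambda1, params = params,
         diagnostics = diagnostics, sampling_interval = sampling_interval),
    class = "lyapunov_estimate"
  )
}

#' @export
print.lyapunov_estimate <- function(x, ...) {
  cat(sprintf("<lyapunov_estimate> method = %s, lambda1 = %.6g nats/time\n",
              x$method, x$lambda1))
  invisible(x)
}

attractor_extent <- function(points) {
  max(apply(points, 2, function(col) diff(range(col))))
}

#' Largest Lyapunov exponent by the Wolf neighbour-replacement method
#'
#' Follows a fiducial trajectory on the reconstructed attractor.  A
#' temporally separated neighbour within `eps_init` (as a fraction of the
#' attractor extent) is evolved together with the fiducial point until
#' their separation exceeds `eps_max` (or `max_evolve` steps elapse);
#' the log stretch \eqn{\ln(\epsilon'_k/\epsilon_k)} is accumulated and
#' a replacement neighbour preserving the separation direction (within
#' `max_angle` radians) is sought.  The exponent is the accumulated log
#' stretch divided by the total evolution time, in nats per unit time.
#'
#' Small negative estimates on non-chaotic data are reported as-is,
#' never clamped.
#'
#' @param embedding a [embed_delay()] reconstruction with >= 500 points.
#' @param eps_init initial separation bound, fraction of attractor
#'   extent (max coordinate range).
#' @param eps_max growth bound before replacement, same units.
#' @param eps_min numerical noise floor: neighbours closer than this
#'   fraction of the extent (near-duplicate points, e.g. on exactly
#'   periodic signals) are never selected.
#' @param theiler minimal temporal separation in samples; default
#'   `tau * m`.
#' @param max_evolve cap on evolution steps per segment (keeps the walk
#'   moving on non-chaotic signals whose separation never grows).
#' @param max_angle replacement angle constraint in radians; widened
#'   (then dropped) when no candidate qualifies.
#' @return A `lyapunov_estimate`; diagnostics include the number of
#'   segments M, the mean evolution time and the fallback count.
#' @export
wolf_lle <- function(embedding, eps_init = 0.02, eps_max = 0.1,
                     eps_min = 1e-6, theiler = NULL, max_evolve = 100,
                     max_angle = 0.3) {
  stopifnot(inherits(embedding, "delay_embedding"))
  E <- embedding$points
  if (nrow(E) < 500) abort("Wolf estimator needs at least 500 embedded points")
  if (!(eps_init > 0 && eps_init < eps_max && eps_max < 1))
    abort("need 0 < eps_init < eps_max < 1 (fractions of attractor extent)")
  theiler <- theiler %||% (embedding$tau * embedding$m)
  check_scalar(theiler, "theiler", lower = 1, integer = TRUE)
  extent <- attractor_extent(E)
  res <- wolf_cpp(E, eps_init * extent, eps_max * extent,
                  eps_min * extent, as.integer(theiler),
                  as.integer(max_evolve), max_angle)
  if (!is.finite(res$sum_log %||% NA_real_) || res$n_segments == 0)
    abort("Wolf estimator found no admissible neighbour to track")
  lambda1 <- res$sum_log / (res$sum_steps * embedding$sampling_interval)
  reliable <- res$n_segments >= 10
  if (!reliable)
    warn(sprintf("only %d replacement segments; Wolf estimate flagged unreliable",
                 res$n_segments))
  new_lyapunov_estimate(
    "wolf", lambda1,
    params = list(eps_init = eps_init, eps_max = eps_max,
                  eps_min = eps_min, theiler = theiler,
                  max_evolve = max_evolve, max_angle = max_angle),
    diagnostics = list(n_segments = res$n_segments,
                       mean_T = res$mean_T * embedding$sampling_interval,
                       n_fallback = res$n_fallback, reliable = reliable),
    sampling_interval = embedding$sampling_interval
  )
}

#' Mean log-divergence curve (Rosenstein method, stage 1)
#'
#' For every reference point the nearest neighbour outside the Theiler
#' window is tracked; the curve stores
#' \eqn{\langle \ln d_j(i) \rangle} against time \eqn{i \Delta t}.
#' Pairs whose trajectories run out of data are dropped from later
#' steps; steps with no surviving pair truncate the grid with a warning.
#'
#' @param embedding a [embed_delay()] reconstruction with >= 500 points.
#' @param max_steps divergence horizon in samples; default
#'   `max(20, K / 10)` capped by the data length.
#' @param theiler minimal temporal separation; default `tau * m`.
#' @return A `divergence_curve`: tibble `(step, time, mean_log_dist,
#'   n_pairs)` with the pair count and parameters as attributes.
#' @export
rosenstein_curve <- function(embedding, max_steps = NULL, theiler = NULL) {
  stopifnot(inherits(embedding, "delay_embedding"))
  E <- embedding$points
  K <- nrow(E)
  if (K < 500) abort("Rosenstein estimator needs at least 500 embedded points")
  theiler <- theiler %||% (embedding$tau * embedding$m)
  check_scalar(theiler, "theiler", lower = 1, integer = TRUE)
  max_steps <- max_steps %||% max(20, floor(K / 10))
  max_steps <- min(max_steps, K - theiler - 2)
  check_scalar(max_steps, "max_steps", lower = 2, integer = TRUE)
  res <- rosenstein_curve_cpp(E, as.integer(theiler), as.integer(max_steps))
  if (res$n_pairs == 0)
    abort("no nonzero-distance neighbour exists outside the Theiler window")
  ok <- res$counts > 0
  if (!all(ok)) {
    warn("divergence grid truncated: all pairs exhausted before max_steps")
    last <- min(which(!ok)) - 1L
    ok <- seq_len(max_steps + 1L) <= last
  }
  steps <- (seq_len(max_steps + 1L) - 1L)[ok]
  curve <- tibble(
    step = steps,
    time = steps * embedding$sampling_interval,
    mean_log_dist = (res$sum_log / pmax(res$counts, 1))[ok],
    n_pairs = as.integer(res$counts)[ok]
  )
  structure(curve,
            class = c("divergence_curve", class(curve)),
            sampling_interval = embedding$sampling_interval,
            n_pairs = res$n_pairs, theiler = theiler)
}

# longest contiguous fit window with R^2 >= r2_min (ties: higher R^2),
# computed over all (start, length) pairs with prefix sums
best_linear_window <- function(t, y, r2_min, min_len) {
  G <- length(y)
  cx <- cumsum(c(0, t)); cy <- cumsum(c(0, y))
  cxx <- cumsum(c(0, t * t)); cxy <- cumsum(c(0, t * y))
  cyy <- cumsum(c(0, y * y))
  best <- NULL
  for (L in seq(min_len, G)) {
    s <- seq_len(G - L + 1)
    e <- s + L - 1
    Sx <- cx[e + 1] - cx[s]; Sy <- cy[e + 1] - cy[s]
    Sxx <- cxx[e + 1] - cxx[s]; Sxy <- cxy[e + 1] - cxy[s]
    Syy <- cyy[e + 1] - cyy[s]
    vx <- Sxx - Sx^2 / L
    vy <- Syy - Sy^2 / L
    cxy_ <- Sxy - Sx * Sy / L
    r2 <- ifelse(vx > 0 & vy > 0, cxy_^2 / (vx * vy), 1)
    hit <- which(r2 >= r2_min)
    if (length(hit)) {
      i <- hit[which.max(r2[hit])]
      cand <- list(start = s[i], end = e[i], r2 = r2[i],
                   slope = cxy_[i] / vx[i], len = L)
      if (is.null(best) || cand$len > best$len ||
          (cand$len == best$len && cand$r2 > best$r2))
        best <- cand
    }
  }
  best
}

#' Largest Lyapunov exponent from a divergence curve (Rosenstein, stage 2)
#'
#' Fits the most linear section of the mean log-divergence curve.  The
#' curve is first restricted to steps retaining at least half of the
#' initial neighbour pairs, then truncated at the earlier of two guards:
#' where it has completed `sat_frac` of its total rise (keeping the
#' plateau out of the fit), and where it has risen `rise_cap` nats above
#' its start (three-quarters of an e-folding of separation growth by
#' default - the horizon within which linearized divergence is
#' trustworthy).  Within
#' that region the longest contiguous window of
#' at least `min_len` points with least-squares \eqn{R^2 \ge} `r2_min`
#' is selected (ties broken by larger \eqn{R^2}); the exponent is its
#' slope in nats per unit time.  When no window qualifies the fit falls
#' back to the first quartile of the grid and the estimate is flagged
#' low-confidence.
#'
#' @param curve a [rosenstein_curve()] result with >= 5 grid points.
#' @param r2_min minimal R^2 for an acceptable window.
#' @param min_len minimal window length in grid points.
#' @param sat_frac fraction of the curve's total rise after which points
#'   are excluded from fitting.
#' @param rise_cap absolute rise (nats) above the curve start after
#'   which points are excluded from fitting.
#' @return A `lyapunov_estimate` with `fit_window` (grid indices),
#'   `fit_r2` and the `low_confidence` flag in its diagnostics.
#' @export
rosenstein_lle <- function(curve, r2_min = 0.98, min_len = 5,
                           sat_frac = 0.7, rise_cap = 0.75) {
  stopifnot(inherits(curve, "divergence_curve"))
  if (nrow(curve) < 5) abort("divergence curve has fewer than 5 grid points")
  si <- attr(curve, "sampling_interval")
  keep <- curve$n_pairs >= 0.5 * curve$n_pairs[1]
  dat <- curve[keep, ]
  y <- dat$mean_log_dist; t <- dat$time
  y0 <- y[1]; ym <- max(y)
  cut_sat <- if (ym > y0) which(y >= y0 + sat_frac * (ym - y0))[1]
             else length(y)
  cut_rise <- if (ym > y0 + rise_cap) which(y >= y0 + rise_cap)[1]
              else length(y)
  cut <- min(cut_sat, cut_rise, na.rm = TRUE)
  cut <- max(cut, min(min_len, length(y)))
  y <- y[seq_len(cut)]; t <- t[seq_len(cut)]
  win <- best_linear_window(t, y, r2_min, min_len)
  low_confidence <- is.null(win)
  if (low_confidence) {
    q <- max(min_len, ceiling(length(curve$time) / 4))
    tq <- curve$time[seq_len(q)]; yq <- curve$mean_log_dist[seq_len(q)]
    fit <- stats::lm(yq ~ tq)
    win <- list(start = 1L, end = q, slope = unname(stats::coef(fit)[2]),
                r2 = summary(fit)$r.squared)
    warn("no linear section met the R^2 criterion; fitted the first quartile of the curve (low confidence)")
  }
  new_lyapunov_estimate(
    "rosenstein", win$slope,
    params = list(r2_min = r2_min, min_len = min_len, sat_frac = sat_frac,
                  rise_cap = rise_cap),
    diagnostics = list(fit_window = c(win$start, win$end), fit_r2 = win$r2,
                       n_grid = nrow(curve), low_confidence = low_confidence),
    sampling_interval = si
  )
}

#' Lyapunov spectrum by the Sano-Sawada local-Jacobian method
#'
#' At each fiducial point the displacement vectors towards its
#' neighbours within a radius (grown geometrically until
#' `min_neighbors` are found) and their images `evolution_m` steps later
#' are related by a local linear map \eqn{A_j}, estimated by least
#' squares from \eqn{A_j V = C}; an orthonormal basis is propagated
#' through the sequence of maps with Gram-Schmidt (QR)
#' reorthonormalisation at every step, and the exponents are the
#' time-averaged log stretches of the basis vectors, in nats per unit
#' time.
#'
#' The default evolution horizon is one map iterate for maps and about
#' 0.15 time units for flows (`max(1, round(0.15 / sampling_interval))`):
#' a one-sample horizon on a finely sampled flow leaves the log
#' stretches dominated by neighbourhood-regression noise, while a
#' horizon of a small fraction of a characteristic orbital period keeps
#' the linearisation valid.
#'
#' Degenerate neighbourhoods are ridge-regularised; fiducial points
#' whose system stays singular are skipped, and more than 50% skips is
#' an error.
#'
#' @param embedding a [embed_delay()] reconstruction with >= 1000 points.
#' @param n_exponents number of exponents (<= embedding dimension);
#'   default the embedding dimension.
#' @param eps initial neighbourhood radius, fraction of attractor extent.
#' @param eps_grow geometric growth factor applied until enough
#'   neighbours are found.
#' @param min_neighbors minimal neighbourhood size; default
#'   `max(10, n_exponents + 1, 2 * m)`.
#' @param evolution_m steps between a neighbourhood and its image.
#' @param ridge ridge scale (times `tr(V)/m`) for degenerate
#'   neighbourhoods.
#' @param zero_tol tolerance for calling an exponent zero in the
#'   classification; default `min(0.3 * |lambda1|, 0.02)`.
#' @return A `lyapunov_spectrum`: descending exponents, KS entropy,
#'   sign classification and diagnostics.
#' @export
sano_sawada_spectrum <- function(embedding, n_exponents = NULL, eps = 0.02,
                                 eps_grow = 1.4, min_neighbors = NULL,
                                 evolution_m = NULL, ridge = 1e-9,
                                 zero_tol = NULL) {
  stopifnot(inherits(embedding, "delay_embedding"))
  E <- embedding$points
  if (nrow(E) < 1000)
    abort("Sano-Sawada estimator needs at least 1000 embedded points")
  m <- embedding$m
  n_exponents <- as.integer(n_exponents %||% m)
  if (n_exponents < 1 || n_exponents > m)
    abort("n_exponents must lie in 1..embedding dimension")
  min_neighbors <- as.integer(min_neighbors %||%
                                max(10, n_exponents + 1, 2 * m))
  if (min_neighbors < n_exponents + 1)
    abort("min_neighbors must be at least n_exponents + 1")
  si <- embedding$sampling_interval
  evolution_m <- as.integer(evolution_m %||% max(1, round(0.15 / si)))
  check_scalar(evolution_m, "evolution_m", lower = 1, integer = TRUE)
  extent <- attractor_extent(E)
  res <- sano_cpp(E, n_exponents, eps * extent, eps_grow,
                  min_neighbors, evolution_m, ridge)
  if (res$n_steps == 0 || res$n_skipped > 0.5 * res$n_fiducial)
    abort(sprintf("Sano-Sawada failed: %d of %d fiducial points skipped",
                  res$n_skipped, res$n_fiducial))
  exponents <- sort(res$lambda_sums / (res$n_steps * evolution_m * si),
                    decreasing = TRUE)
  new_lyapunov_spectrum(
    exponents, zero_tol = zero_tol, method = "sano_sawada",
    params = list(eps = eps, min_neighbors = min_neighbors,
                  evolution_m = evolution_m, ridge = ridge,
                  n_exponents = n_exponents),
    diagnostics = list(n_steps = res$n_steps, n_skipped = res$n_skipped,
                       n_fiducial = res$n_fiducial),
    sampling_interval = si
  )
}

new_lyapunov_spectrum <- function(exponents, zero_tol = NULL,
                                  method = "sano_sawada", params = list(),
                                  diagnostics = list(),
                                  sampling_interval = 1) {
  exponents <- sort(as.double(exponents), decreasing = TRUE)
  zero_tol <- zero_tol %||% min(0.3 * abs(exponents[1]), 0.02)
  h <- sum(exponents[exponents > zero_tol])
  structure(
    list(exponents = exponents, ks_entropy = h,
         classification = sign_string(exponents, zero_tol),
         zero_tol = zero_tol, method = method, params = params,
         diagnostics = diagnostics, sampling_interval = sampling_interval),
    class = "lyapunov_spectrum"
  )
}

#' Construct a Lyapunov spectrum from known exponents
#'
#' Mostly for downstream use of [ks_entropy()] and
#' [classify_attractor()] with exponents from any source.
#'
#' @param exponents numeric vector of exponents (any order).
#' @param zero_tol zero-classification tolerance; default
#'   `min(0.3 * |lambda1|, 0.02)`.
#' @return A `lyapunov_spectrum`.
#' @export
lyapunov_spectrum <- function(exponents, zero_tol = NULL) {
  new_lyapunov_spectrum(exponents, zero_tol = zero_tol, method = "manual")
}

sign_string <- function(exponents, zero_tol) {
  paste(vapply(exponents, function(l) {
    if (abs(l) <= zero_tol) "0" else if (l > 0) "+" else "-"
  }, ""), collapse = "")
}

#' @export
print.lyapunov_spectrum <- function(x, ...) {
  cat(sprintf("<lyapunov_spectrum> (%s)  [%s]\n",
              paste(sprintf("%.5g", x$exponents), collapse = ", "),
              x$classification))
  cat(sprintf("  KS entropy %.5g nats/time; zero tolerance %.3g\n",
              x$ks_entropy, x$zero_tol))
  invisible(x)
}

#' Kolmogorov-Sinai entropy of a Lyapunov spectrum
#'
#' The sum of the strictly positive exponents (those above the zero
#' tolerance): the rate at which the system loses information about its
#' initial state.  Positive KS entropy marks chaos; zero with a zero
#' exponent marks regular (periodic or quasiperiodic) motion; all
#' exponents negative marks a stable fixed point.
#'
#' @param spectrum a `lyapunov_spectrum` or a numeric vector of
#'   exponents.
#' @param zero_tol threshold above which an exponent counts as positive
#'   (default: the spectrum's own tolerance, or 0 for numeric input).
#' @return KS entropy in nats per unit time.
#' @examples
#' ks_entropy(c(0.5, -1))      # 0.5
#' ks_entropy(c(0.1, 0.2, -3)) # 0.3
#' @export
ks_entropy <- function(spectrum, zero_tol = NULL) {
  if (inherits(spectrum, "lyapunov_spectrum")) {
    exps <- spectrum$exponents
    zero_tol <- zero_tol %||% spectrum$zero_tol
  } else {
    exps <- as.double(spectrum)
    zero_tol <- zero_tol %||% 0
  }
  sum(exps[exps > zero_tol])
}

#' Classify an attractor from the signs of its Lyapunov spectrum
#'
#' Maps the sign pattern (with a zero tolerance) to the standard
#' taxonomy: in 1D a stable fixed point (-); in 2D a stable fixed point
#' (-,-) or limit cycle (0,-); in 3D a stable fixed point (-,-,-), limit
#' cycle (0,-,-), 2-torus (0,0,-) or strange attractor (+,0,-).  Any
#' other pattern (or more than 3 exponents) is reported as
#' "unclassified" alongside the raw sign string.
#'
#' @param spectrum a `lyapunov_spectrum` or numeric exponents.
#' @param zero_tol zero tolerance; default `min(0.3 * |lambda1|, 0.02)`.
#' @return A list with `class` and the `signs` string.
#' @export
classify_attractor <- function(spectrum, zero_tol = NULL) {
  if (!inherits(spectrum, "lyapunov_spectrum"))
    spectrum <- lyapunov_spectrum(spectrum, zero_tol = zero_tol)
  else if (!is.null(zero_tol))
    spectrum <- lyapunov_spectrum(spectrum$exponents, zero_tol = zero_tol)
  signs <- spectrum$classification
  cls <- switch(signs,
    "-"   = "stable fixed point",
    "--"  = "stable fixed point",
    "0-"  = "stable limit cycle",
    "---" = "stable fixed point",
    "0--" = "stable limit cycle",
    "00-" = "stable 2-torus",
    "+0-" = "strange attractor",
    "unclassified"
  )
  list(class = cls, signs = signs, zero_tol = spectrum$zero_tol)
}
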