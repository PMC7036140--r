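#' Analysis configuration for the channel-wise EEG pipeline
#'
#' Collects and validates every tunable of the per-channel metric
#' computation.  Defaults are the package's EEG working set: automatic
#' embedding (MI delay, FNN dimension, capped at `m_max`), a 7-exponent
#' Sano-Sawada spectrum (which floors the embedding dimension at 7),
#' and the multiscale-entropy parameter set `m = 20`, `r = 0.4`,
#' `d = 3`.
#'
#' @param tau_max,n_bins,m_max,rtol,atol,fnn_threshold embedding stage.
#' @param theiler Theiler window in samples (`NULL`: `tau * m`).
#' @param eps_init,eps_max,max_evolve,max_angle Wolf stage.
#' @param ros_max_steps,r2_min,sat_frac Rosenstein stage.
#' @param sano_eps,min_neighbors,n_exponents,evolution_m Sano-Sawada
#'   stage (`NULL`s: estimator defaults).
#' @param mse_m,mse_r,mse_d multiscale-entropy stage.
#' @return An `analysis_config` list.
#' @export
analysis_config <- function(tau_max = 25, n_bins = 16, m_max = 8,
                            rtol = 10, atol = 2, fnn_threshold = 0.01,
                            theiler = NULL,
                            eps_init = 0.02, eps_max = 0.1,
                            max_evolve = 100, max_angle = 0.3,
                            ros_max_steps = 100, r2_min = 0.98,
                            sat_frac = 0.7,
                            sano_eps = 0.02, min_neighbors = NULL,
                            n_exponents = 7, evolution_m = NULL,
                            mse_m = 20, mse_r = 0.4, mse_d = 3) {
  check_scalar(tau_max, "tau_max", lower = 2, integer = TRUE)
  check_scalar(n_bins, "n_bins", lower = 4, integer = TRUE)
  check_scalar(m_max, "m_max", lower = 1, integer = TRUE)
  check_scalar(fnn_threshold, "fnn_threshold", lower = 0, upper = 1)
  check_scalar(eps_init, "eps_init", lower = 0, upper = 1, open_lower = TRUE)
  check_scalar(eps_max, "eps_max", lower = eps_init, upper = 1)
  check_scalar(r2_min, "r2_min", lower = 0, upper = 1)
  check_scalar(sat_frac, "sat_frac", lower = 0, upper = 1, open_lower = TRUE)
  check_scalar(n_exponents, "n_exponents", lower = 1, integer = TRUE)
  check_scalar(mse_m, "mse_m", lower = 1, integer = TRUE)
  check_scalar(mse_r, "mse_r", lower = 0, open_lower = TRUE)
  check_scalar(mse_d, "mse_d", lower = 1, integer = TRUE)
  structure(
    list(tau_max = tau_max, n_bins = n_bins, m_max = m_max, rtol = rtol,
         atol = atol, fnn_threshold = fnn_threshold, theiler = theiler,
         eps_init = eps_init, eps_max = eps_max, max_evolve = max_evolve,
         max_angle = max_angle, ros_max_steps = ros_max_steps,
         r2_min = r2_min, sat_frac = sat_frac, sano_eps = sano_eps,
         min_neighbors = min_neighbors, n_exponents = n_exponents,
         evolution_m = evolution_m, mse_m = mse_m, mse_r = mse_r,
         mse_d = mse_d),
    class = "analysis_config"
  )
}

#' Channel-wise nonlinear metrics of a recording
#'
#' Applies the full metric set to every channel: automatic delay
#' embedding, the largest Lyapunov exponent by the Wolf and Rosenstein
#' methods, the Sano-Sawada spectrum (Le1..Le7 by default) with KS
#' entropy, multiscale entropy, and normalized Lempel-Ziv complexity.
#' Per-channel failures are recorded (NA cells plus a note in the
#' diagnostics attribute) and never abort the table.
#'
#' @param rec an `eeg_recording`.
#' @param config an [analysis_config()].
#' @param metrics subset of `c("wolf", "rosenstein", "sano", "mse",
#'   "lzc")` to compute.
#' @return A `channel_metrics` tibble, one row per channel, with the
#'   chosen `tau`/`m` per channel and the recording label attached; the
#'   per-cell diagnostics live in `attr(, "diagnostics")`.
#' @export
per_channel_metrics <- function(rec, config = analysis_config(),
                                metrics = c("wolf", "rosenstein", "sano",
                                            "mse", "lzc")) {
  stopifnot(inherits(rec, "eeg_recording"),
            inherits(config, "analysis_config"))
  metrics <- match.arg(metrics, several.ok = TRUE)
  diagnostics <- list()
  rows <- purrr::map(rec$channel_names, function(ch) {
    series <- scalar_series(rec$data[, ch], sampling_interval = 1 / rec$fs,
                            label = ch)
    row <- list(channel = ch)
    notes <- list()
    emb <- NULL
    need_embedding <- any(c("wolf", "rosenstein", "sano") %in% metrics)
    if (need_embedding) {
      emb <- tryCatch(
        suppressWarnings(select_embedding(
          series, tau_max = config$tau_max, n_bins = config$n_bins,
          m_max = config$m_max, rtol = config$rtol, atol = config$atol,
          fnn_threshold = config$fnn_threshold,
          min_m = if ("sano" %in% metrics) config$n_exponents else 1
        )),
        error = function(e) { notes$embedding <<- conditionMessage(e); NULL }
      )
      row$tau <- if (is.null(emb)) NA_integer_ else emb$tau
      row$dim_m <- if (is.null(emb)) NA_integer_ else emb$m
    }
    theiler <- config$theiler
    cell <- function(expr) {
      tryCatch(suppressWarnings(expr), error = function(e) {
        structure(NA_real_, note = conditionMessage(e))
      })
    }
    if ("wolf" %in% metrics) {
      v <- if (is.null(emb)) NA_real_ else cell(
        wolf_lle(emb$embedding, eps_init = config$eps_init,
                 eps_max = config$eps_max, theiler = theiler,
                 max_evolve = config$max_evolve,
                 max_angle = config$max_angle)$lambda1)
      if (!is.null(attr(v, "note"))) notes$wolf <- attr(v, "note")
      row$wolf_le1 <- as.numeric(v)
    }
    if ("rosenstein" %in% metrics) {
      v <- if (is.null(emb)) NA_real_ else cell({
        crv <- rosenstein_curve(emb$embedding,
                                max_steps = config$ros_max_steps,
                                theiler = theiler)
        rosenstein_lle(crv, r2_min = config$r2_min,
                       sat_frac = config$sat_frac)$lambda1
      })
      if (!is.null(attr(v, "note"))) notes$rosenstein <- attr(v, "note")
      row$rosenstein_le1 <- as.numeric(v)
    }
    if ("sano" %in% metrics) {
      sp <- if (is.null(emb)) NULL else cell(
        sano_sawada_spectrum(emb$embedding,
                             n_exponents = config$n_exponents,
                             eps = config$sano_eps,
                             min_neighbors = config$min_neighbors,
                             evolution_m = config$evolution_m))
      if (!is.null(attr(sp, "note"))) notes$sano <- attr(sp, "note")
      exps <- if (inherits(sp, "lyapunov_spectrum")) sp$exponents
              else rep(NA_real_, config$n_exponents)
      for (i in seq_len(config$n_exponents))
        row[[paste0("sano_le", i)]] <- exps[i]
      row$ks_entropy <- if (inherits(sp, "lyapunov_spectrum"))
        sp$ks_entropy else NA_real_
    }
    if ("mse" %in% metrics) {
      prof <- cell(multiscale_entropy(series, m = config$mse_m,
                                      r = config$mse_r, d = config$mse_d))
      if (!is.null(attr(prof, "note"))) notes$mse <- attr(prof, "note")
      ent <- if (inherits(prof, "mse_profile")) prof$entropy
             else rep(NA_real_, config$mse_d)
      for (i in seq_len(config$mse_d))
        row[[paste0("mse_scale", i)]] <- ent[i]
    }
    if ("lzc" %in% metrics) {
      v <- cell(lempel_ziv_complexity(series)$lzc)
      if (!is.null(attr(v, "note"))) notes$lzc <- attr(v, "note")
      row$lzc <- as.numeric(v)
    }
    if (length(notes)) diagnostics[[ch]] <<- notes
    tibble::as_tibble(row)
  })
  out <- dplyr::bind_rows(rows)
  structure(out, class = c("channel_metrics", class(out)),
            label = rec$label, fs = rec$fs, config = config,
            metrics = metrics, diagnostics = diagnostics)
}

#' Channel-averaged value of one metric
#'
#' Arithmetic mean over channels of one `channel_metrics` column,
#' non-finite cells (failed or infinite-entropy channels) excluded; the
#' number of exclusions is attached as an attribute and must leave at
#' least one finite cell.
#'
#' @param table a `channel_metrics` tibble.
#' @param metric column name.
#' @return The mean, with attribute `n_excluded`.
#' @export
channel_average <- function(table, metric) {
  stopifnot(inherits(table, "channel_metrics"))
  if (!metric %in% names(table))
    abort(sprintf("unknown metric column `%s`", metric))
  v <- table[[metric]]
  finite <- is.finite(v)
  if (!any(finite)) abort(sprintf("no finite `%s` cell to average", metric))
  structure(mean(v[finite]), n_excluded = sum(!finite))
}

#' Longitudinal trend of a channel-averaged metric
#'
#' Orders the recordings by their labels as given, averages the metric
#' across channels per recording, and marks interior local extrema
#' (strictly greater/less than both neighbours).
#'
#' @param tables list of `channel_metrics` tables with distinct labels.
#' @param metric column name.
#' @return A `trend_series` tibble `(label, value, n_excluded,
#'   is_local_min, is_local_max)`.
#' @export
longitudinal_trend <- function(tables, metric) {
  if (length(tables) < 2)
    abort("a trend needs at least 2 recordings")
  labels <- vapply(tables, function(tb) attr(tb, "label"), "")
  if (anyDuplicated(labels))
    abort("recording labels must be distinct")
  vals <- lapply(tables, channel_average, metric = metric)
  value <- vapply(vals, as.numeric, 0)
  n_excluded <- vapply(vals, function(v) attr(v, "n_excluded"), 0)
  n <- length(value)
  is_min <- is_max <- rep(FALSE, n)
  if (n >= 3) {
    for (i in 2:(n - 1)) {
      is_min[i] <- value[i] < value[i - 1] && value[i] < value[i + 1]
      is_max[i] <- value[i] > value[i - 1] && value[i] > value[i + 1]
    }
  }
  out <- tibble(label = labels, value = value, n_excluded = n_excluded,
                is_local_min = is_min, is_local_max = is_max)
  structure(out, class = c("trend_series", class(out)), metric = metric)
}

#' Serialize a metric table to JSON
#'
#' Deterministic serialization (fixed digits, stable column order) so
#' that identical analyses produce byte-identical files.
#'
#' @param table a `channel_metrics` tibble.
#' @param path output path; `NULL` returns the JSON string.
#' @return The JSON string, invisibly when written to a file.
#' @export
write_metrics_json <- function(table, path = NULL) {
  stopifnot(inherits(table, "channel_metrics"))
  payload <- list(
    label = attr(table, "label"),
    fs = attr(table, "fs"),
    metrics = as.data.frame(table),
    interpretation = paste(
      "Working interpretation stored with every report: a decrease in",
      "entropy and an increase in the Lempel-Ziv complexity are read as",
      "a decrease in the signal randomness."),
    diagnostics = attr(table, "diagnostics")
  )
  json <- jsonlite::toJSON(payload, digits = NA, auto_unbox = TRUE,
                           na = "null")
  if (is.null(path)) return(json)
  writeLines(json, path)
  invisible(json)
}
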