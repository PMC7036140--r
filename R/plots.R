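#' @export
autoplot.divergence_curve <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(x = .data$time, y = .data$mean_log_dist)) +
    ggplot2::geom_line(color = "steelblue") +
    ggplot2::geom_point(size = 0.6) +
    ggplot2::labs(x = "time", y = "<ln d(i)>",
                  title = "Mean log-divergence of nearest-neighbour pairs") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.mse_profile <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(x = .data$scale, y = .data$entropy)) +
    ggplot2::geom_line(color = "steelblue") +
    ggplot2::geom_point() +
    ggplot2::labs(x = "scale", y = "sample entropy (nats)",
                  title = "Multiscale entropy") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.trend_series <- function(object, ...) {
  d <- tidy(object)
  d$label <- factor(d$label, levels = d$label)
  extrema <- d[d$is_local_min | d$is_local_max, ]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$label, y = .data$value,
                                  group = 1)) +
    ggplot2::geom_line(color = "steelblue") +
    ggplot2::geom_point() +
    ggplot2::geom_point(data = extrema, color = "red", size = 2.5) +
    ggplot2::labs(x = NULL, y = attr(object, "metric"),
                  title = "Channel-averaged trend (local extrema in red)") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.topo_map <- function(object, ...) {
  ggplot2::ggplot(object$grid,
                  ggplot2::aes(x = .data$x, y = .data$y,
                               fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::geom_point(data = object$electrodes,
                        ggplot2::aes(x = .data$x, y = .data$y),
                        inherit.aes = FALSE, shape = 21, fill = "white",
                        size = 1.6) +
    ggplot2::geom_text(data = object$electrodes,
                       ggplot2::aes(x = .data$x, y = .data$y,
                                    label = .data$channel),
                       inherit.aes = FALSE, size = 2.4, vjust = -1) +
    ggplot2::scale_fill_gradientn(
      colors = c("darkblue", "blue", "cyan", "green", "yellow",
                 "orange", "red", "darkred"),
      na.value = "transparent") +
    ggplot2::coord_equal() +
    ggplot2::labs(title = object$metric %||% "scalp topography",
                  x = NULL, y = NULL) +
    ggplot2::theme_void()
}

#' Channel profile of one metric
#'
#' Line plot of a `channel_metrics` column across the 21 channels in
#' canonical montage order — the per-channel view in which focal
#' abnormalities appear as local extrema.
#'
#' @param table a `channel_metrics` tibble.
#' @param metric column to plot.
#' @return A ggplot.
#' @export
plot_channel_profile <- function(table, metric) {
  stopifnot(inherits(table, "channel_metrics"))
  d <- tibble(channel = factor(table$channel, levels = table$channel),
              value = table[[metric]])
  ggplot2::ggplot(d, ggplot2::aes(x = .data$channel, y = .data$value,
                                  group = 1)) +
    ggplot2::geom_line(color = "steelblue") +
    ggplot2::geom_point() +
    ggplot2::labs(x = NULL, y = metric, title = attr(table, "label")) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}
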