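#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot an angular histogram as a polar rose
#'
#' @param hist A [polar_histogram()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot_polar_histogram <- function(hist, ...) {
  stopifnot(inherits(hist, "polar_histogram"))
  mid <- (hist$bin_edges[-1] + hist$bin_edges[-length(hist$bin_edges)]) / 2
  df <- tibble::tibble(angle = mid, frequency = hist$frequencies)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$angle, y = .data$frequency)) +
    ggplot2::geom_col(width = 2 * pi / hist$n_bins, fill = "steelblue",
                      colour = "grey30") +
    ggplot2::geom_hline(yintercept = 1 / hist$n_bins, linetype = 2) +
    ggplot2::coord_polar(start = pi / 2, direction = -1) +
    ggplot2::scale_x_continuous(limits = c(-pi, pi),
                                breaks = seq(-pi, pi / 2, by = pi / 2),
                                labels = c("-π", "-π/2", "0",
                                           "π/2")) +
    ggplot2::labs(x = NULL, y = "frequency") +
    ggplot2::theme_minimal()
}

#' Scatter plot of a Golgi screen: dispersion vs fragmentation
#'
#' Normalized PDS on the x-axis against normalized fragment count on the
#' y-axis, one point per treatment; the control sits at (1, 1).
#'
#' @param object A `golgi_screen`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot golgi_screen
#' @export
autoplot.golgi_screen <- function(object, ...) {
  df <- object$per_treatment
  ggplot2::ggplot(df, ggplot2::aes(x = .data$normalized_pds,
                                   y = .data$norm_fragment_count)) +
    ggplot2::geom_hline(yintercept = 1, linetype = 3, colour = "grey60") +
    ggplot2::geom_vline(xintercept = 1, linetype = 3, colour = "grey60") +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_text(ggplot2::aes(label = .data$treatment),
                       vjust = -0.8, size = 3) +
    ggplot2::labs(x = "normalized polar distribution score",
                  y = "normalized fragment count",
                  subtitle = paste0("r = ", round(object$correlation_r, 3))) +
    ggplot2::theme_classic()
}

#' Bar plot of a carrier screen as percent of control
#'
#' @param object A `carrier_screen`.
#' @param metric `"speed"` or `"displacement"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot carrier_screen
#' @export
autoplot.carrier_screen <- function(object,
                                    metric = c("speed", "displacement"),
                                    ...) {
  metric <- match.arg(metric)
  col <- if (metric == "speed") "pct_speed_of_control" else
    "pct_displacement_of_control"
  df <- object$per_treatment
  ggplot2::ggplot(df, ggplot2::aes(x = stats::reorder(.data$treatment,
                                                      .data[[col]]),
                                   y = .data[[col]])) +
    ggplot2::geom_col(fill = "grey40") +
    ggplot2::geom_hline(yintercept = 100, linetype = 2) +
    ggplot2::labs(x = NULL, y = paste0("mean ", metric, " (% of ",
                                       object$control, ")")) +
    ggplot2::theme_classic()
}
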