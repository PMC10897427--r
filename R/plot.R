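# ggplot2 visualisations of the package's result objects.

#' @export
autoplot.ipan_run_summary <- function(object, ...) {
  curves <- object$curves |>
    tidyr::pivot_longer(c("dorsal", "ventral"), names_to = "layer",
                        values_to = "count")
  p <- ggplot2::ggplot(curves,
                       ggplot2::aes(x = .data$t_min, y = .data$count,
                                    colour = .data$layer)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(shape = 17, size = 1.6) +
    ggplot2::scale_colour_manual(
      values = c(dorsal = "#E69F00", ventral = "#009E73")
    ) +
    ggplot2::labs(
      x = "time (min)", y = "cumulative mitotic cells", colour = NULL,
      title = sprintf("%s (seed %s)", object$scenario, object$seed)
    ) +
    ggplot2::theme_minimal()
  if (!is.null(object$ratios)) {
    sc <- max(1e-9, max(curves$count)) / max(1e-9, max(object$ratios$ratio))
    p <- p +
      ggplot2::geom_line(
        data = object$ratios,
        ggplot2::aes(x = .data$t_min, y = .data$ratio * sc),
        colour = "#CC3399", inherit.aes = FALSE
      ) +
      ggplot2::scale_y_continuous(
        sec.axis = ggplot2::sec_axis(~ . / sc, name = "interepithelial MT ratio")
      )
  }
  p
}

#' @export
autoplot.ipan_scenario_report <- function(object, ...) {
  dat <- as_tibble(object)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$metric, y = .data$mean)) +
    ggplot2::geom_point() +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$ci_lo, ymax = .data$ci_hi), width = 0.2
    ) +
    ggplot2::facet_wrap(~metric, scales = "free") +
    ggplot2::labs(
      x = NULL, y = "mean across replicates (95% bootstrap CI)",
      title = attr(object, "scenario")
    ) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
}

#' Plot a ratio time series
#'
#' @param ratios Output of [ratio_timeseries()].
#' @return A ggplot object.
#' @export
plot_ratio_timeseries <- function(ratios) {
  ggplot2::ggplot(ratios, ggplot2::aes(x = .data$t_min, y = .data$ratio)) +
    ggplot2::geom_line(colour = "#CC3399") +
    ggplot2::geom_point(colour = "#CC3399", size = 1.2) +
    ggplot2::labs(x = "time (min)", y = "interepithelial MT ratio") +
    ggplot2::theme_minimal()
}
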