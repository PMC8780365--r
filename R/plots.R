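#' Plot a density grid
#'
#' Raster heatmap of an occupancy/crowd density map (or a 0/1 region grid)
#' in top-view metres.
#'
#' @param object A `density_grid`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.density_grid <- function(object, ...) {
  df <- as_tibble.density_grid(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "density") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (m)", y = "y (m)") +
    ggplot2::theme_minimal()
}

#' Plot a pipeline run as a top-view map
#'
#' Tracked trajectories over the averaged crowd density map, with violating
#' positions highlighted.
#'
#' @param object A `crowd_run` from [run_pipeline()].
#' @param density Which background map to show: `"cdm"`, `"odm"` or
#'   `"none"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.crowd_run <- function(object, density = c("cdm", "odm", "none"), ...) {
  density <- match.arg(density)
  p <- ggplot2::ggplot()
  if (density != "none") {
    bg <- as_tibble.density_grid(object[[density]])
    p <- p + ggplot2::geom_raster(
      data = bg, ggplot2::aes(.data$x, .data$y, fill = .data$value)
    ) +
      ggplot2::scale_fill_viridis_c(name = density)
  }
  res <- object$results
  p +
    ggplot2::geom_path(
      data = res,
      ggplot2::aes(.data$x, .data$y, group = .data$id),
      colour = "grey80", linewidth = 0.3
    ) +
    ggplot2::geom_point(
      data = res,
      ggplot2::aes(.data$x, .data$y,
                   colour = factor(.data$violating, levels = c(0, 1))),
      size = 0.6
    ) +
    ggplot2::scale_colour_manual(
      name = "violating", values = c(`0` = "seagreen3", `1` = "red2"),
      drop = FALSE
    ) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (m)", y = "y (m)") +
    ggplot2::theme_minimal()
}

#' Plot evaluation metrics across a safety-distance sweep
#'
#' @param eval_tbl Output of [evaluate_run()] over several safety distances.
#' @param metrics Metric columns to draw.
#' @return A ggplot object.
#' @export
plot_safety_sweep <- function(eval_tbl,
                              metrics = c("accuracy", "f1", "vcr", "iou")) {
  metrics <- intersect(metrics, names(eval_tbl))
  df <- tidyr::pivot_longer(eval_tbl[c("r", metrics)], -"r",
                            names_to = "metric", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(.data$r, .data$value,
                                   colour = .data$metric)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "safety distance r (m)", y = "metric value") +
    ggplot2::theme_minimal()
}
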