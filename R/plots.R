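#' Plot the line-fit decode of a phase difference
#'
#' The algorithmic decoder's picture: unwrapped phase differences of the
#' best candidate against inverse module scale, with the fitted line
#' through the origin whose gradient is `2 * pi * d`.
#'
#' @param dp a `phase_diff`.
#' @param sys a [grid_system()].
#' @param axis axis index.
#' @return a ggplot.
#' @export
plot_linefit <- function(dp, sys, axis = 1) {
  rep <- decode_linefit(dp, sys, axis = axis)
  s <- axis_scales(sys, axis)
  pts <- tibble(
    inv_scale = 1 / s,
    unwrapped = dp[[c("dp_x", "dp_y")[axis]]] + TWO_PI * rep$n[[1]]
  )
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$inv_scale, y = .data$unwrapped)) +
    ggplot2::geom_abline(intercept = 0, slope = TWO_PI * rep$d_cm,
                         colour = "grey50") +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(
      x = "inverse grid scale (1/cm)",
      y = "unwrapped phase difference (rad)",
      title = sprintf("axis %d: d = %.2f cm (rms misfit %.2g rad)",
                      axis, rep$d_cm, rep$residual)
    ) +
    ggplot2::theme_minimal()
}

#' Plot a grid cell's hexagonal rate map
#'
#' @param module one-row slice of a [grid_system()].
#' @param cell_phase_offset the cell's phase offset pair in radians.
#' @param extent half-width of the plotted square in cm (default two
#'   scales).
#' @param n raster resolution per side.
#' @return a ggplot.
#' @export
plot_rate_map <- function(module, cell_phase_offset = c(0, 0),
                          extent = 2 * module$scale_cm, n = 121) {
  xs <- seq(-extent, extent, length.out = n)
  grid <- tidyr::expand_grid(x_cm = xs, y_cm = xs)
  grid$rate <- rate_map(cell_phase_offset, grid, module)
  ggplot2::ggplot(grid, ggplot2::aes(.data$x_cm, .data$y_cm,
                                     fill = .data$rate)) +
    ggplot2::geom_raster() +
    ggplot2::coord_equal() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::labs(x = "x (cm)", y = "y (cm)", fill = "rate") +
    ggplot2::theme_minimal()
}

#' Plot benchmark decode errors by model
#'
#' @param object a `nav_benchmark`.
#' @param ... unused.
#' @return a ggplot.
#' @exportS3Method
autoplot.nav_benchmark <- function(object, ...) {
  ggplot2::ggplot(object$records,
                  ggplot2::aes(x = .data$model, y = .data$error_cm)) +
    ggplot2::geom_boxplot(outlier.size = 0.6) +
    ggplot2::labs(x = NULL, y = "decode error (cm)") +
    ggplot2::theme_minimal()
}

#' Plot look-ahead latency against true distance
#'
#' The defining behavioural signature of the look-ahead decoder: steps to
#' coincidence grow linearly (through the origin) with the length of the
#' translation vector along the swept axes.
#'
#' @param bench a `nav_benchmark` run with the `lookahead` model.
#' @return a ggplot.
#' @export
plot_latency <- function(bench) {
  la <- bench$records |> filter(.data$model == "lookahead", .data$success)
  la$axis_distance_cm <- abs(la$true_d1) + abs(la$true_d2)
  ggplot2::ggplot(la, ggplot2::aes(.data$axis_distance_cm,
                                   .data$latency_steps)) +
    ggplot2::geom_abline(intercept = 0, slope = 1 / bench$step_size,
                         colour = "grey60") +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "|d1| + |d2| (cm)", y = "steps to coincidence") +
    ggplot2::theme_minimal()
}
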