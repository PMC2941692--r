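# ggplot2 views of model components. These are diagnostic projections
# (the 3D scene export is the rendering path); autoplot methods follow
# the broom/ggplot2 convention of returning a customizable ggplot.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a nuclear walk as a 2D projection
#'
#' @param object A `nuclear_path`.
#' @param ... Unused.
#' @return A ggplot: x-y projection of the walk, colored by giant loop,
#'   with the nuclear envelope circle.
#' @export
autoplot.nuclear_path <- function(object, ...) {
  radius <- attr(object, "params")$nucleus_radius_nm
  circle <- tibble(
    t = seq(0, 2 * pi, length.out = 200),
    x = radius * cos(seq(0, 2 * pi, length.out = 200)),
    y = radius * sin(seq(0, 2 * pi, length.out = 200))
  )
  ggplot2::ggplot(object, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_path(ggplot2::aes(color = factor(.data$loop)),
                       linewidth = 0.3, na.rm = TRUE) +
    ggplot2::geom_path(data = circle, linetype = "dashed",
                       color = "grey50") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (nm)", y = "y (nm)", color = "giant loop",
                  title = "Nuclear-scale giant-loop random walk") +
    ggplot2::theme_minimal()
}

#' Plot a fiber path projection
#'
#' @param object A `fiber_path`.
#' @param ... Unused.
#' @return A ggplot of the x-y projection colored by genomic position.
#' @export
autoplot.fiber_path <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$x, y = .data$y,
                                       color = .data$bp / 1e6)) +
    ggplot2::geom_path(linewidth = 0.3) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (nm)", y = "y (nm)", color = "Mbp",
                  title = "30 nm fiber path") +
    ggplot2::theme_minimal()
}

#' Plot a projected annotation along the chromosome
#'
#' @param object A `scale_annotation` from [project()].
#' @param ... Unused.
#' @return A ggplot of aggregated value versus element bp midpoint.
#' @export
autoplot.scale_annotation <- function(object, ...) {
  df <- as_tibble(object)
  df$mid <- (df$bp_start + df$bp_end) / 2
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mid / 1e3, y = .data$value,
                                   color = .data$type)) +
    ggplot2::geom_step(na.rm = TRUE) +
    ggplot2::labs(
      x = "position (kbp)",
      y = paste0(attr(object, "aggregation"), " value"),
      title = sprintf("Annotation at %s scale", attr(object, "scale"))
    ) +
    ggplot2::theme_minimal()
}

#' Tidy an annotation into a plain tibble
#'
#' @param x A `scale_annotation`.
#' @param ... Unused.
#' @return The underlying tibble with `scale` and `aggregation` columns.
#' @export
tidy.scale_annotation <- function(x, ...) {
  dplyr::bind_cols(
    tibble(scale = attr(x, "scale"), aggregation = attr(x, "aggregation")),
    as_tibble(x)
  )
}
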