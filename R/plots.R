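#' Plot a fitted genetic-influence map
#'
#' Convenience figure: grid nodes coloured by the fitted local PGS
#' coefficient on a diverging low-to-high (blue to red) scale, with a
#' histogram of node values coloured the same way. Requires ggplot2
#' (Suggests); figures are a convenience output, not part of the
#' analysis surface.
#'
#' @param map A `local_fit_map` (or any data frame with `x`, `y` and a
#'   value column).
#' @param value Value column to plot (default `"beta"`).
#' @param region Optional `study_region` to draw as an outline.
#' @return A `pgsmap_figure`: list of two ggplot objects (`map`,
#'   `histogram`) whose print method draws them side by side.
#' @export
plot_fit_map <- function(map, value = "beta", region = NULL) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    pgsmap_error("plot_fit_map requires the ggplot2 package", "pgsmap_config_error")
  }
  df <- as.data.frame(map)
  pd <- data.frame(x = df$x, y = df$y, v = df[[value]])
  mid <- stats::median(pd$v, na.rm = TRUE)
  p_map <- ggplot2::ggplot(pd, ggplot2::aes(x, y, colour = v)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::scale_colour_gradient2(low = "blue", mid = "grey90", high = "red",
                                    midpoint = mid) +
    ggplot2::coord_equal() +
    ggplot2::labs(colour = value, x = NULL, y = NULL) +
    ggplot2::theme_minimal()
  if (!is.null(region)) {
    ring <- data.frame(rx = c(region$vertices[, 1], region$vertices[1, 1]),
                       ry = c(region$vertices[, 2], region$vertices[1, 2]))
    p_map <- p_map + ggplot2::geom_path(
      data = ring, ggplot2::aes(rx, ry), inherit.aes = FALSE, colour = "grey40"
    )
  }
  p_hist <- ggplot2::ggplot(pd, ggplot2::aes(v, fill = ggplot2::after_stat(x))) +
    ggplot2::geom_histogram(bins = 40) +
    ggplot2::scale_fill_gradient2(low = "blue", mid = "grey90", high = "red",
                                  midpoint = mid, guide = "none") +
    ggplot2::labs(x = value, y = "nodes") +
    ggplot2::theme_minimal()
  structure(list(map = p_map, histogram = p_hist), class = "pgsmap_figure")
}

#' @export
print.pgsmap_figure <- function(x, ...) {
  grid::grid.newpage()
  grid::pushViewport(grid::viewport(layout = grid::grid.layout(1, 2)))
  print(x$map, vp = grid::viewport(layout.pos.row = 1, layout.pos.col = 1))
  print(x$histogram, vp = grid::viewport(layout.pos.row = 1, layout.pos.col = 2))
  grid::popViewport()
  invisible(x)
}
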