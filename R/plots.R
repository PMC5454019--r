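#' Cytometry-style scatter of object NFRET versus object Pearson
#'
#' The two discriminating coordinates plotted against each other, one
#' point per object, sized by object area and colored by the deposition
#' label when present. Co-localized, interacting structures populate the
#' upper-right quadrant; distinct structures cluster around the origin.
#'
#' @param object A `fretcoloc_analysis` (or an object table tibble via
#'   [plot_objects()]).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.fretcoloc_analysis <- function(object, ...) {
  plot_objects(object$objects) +
    ggplot2::labs(title = object$source_id)
}

#' @rdname autoplot.fretcoloc_analysis
#' @param table An object table tibble (e.g. from [tidy()] or a batch
#'   combined table).
#' @export
plot_objects <- function(table) {
  stopifnot(is.data.frame(table))
  p <- ggplot2::ggplot(table, ggplot2::aes(x = .data$pearson, y = .data$mean_NFRET)) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dotted", colour = "grey50") +
    ggplot2::geom_vline(xintercept = 0, linetype = "dotted", colour = "grey50")
  if ("label" %in% names(table)) {
    p <- p + ggplot2::geom_point(
      ggplot2::aes(size = .data$area_px, colour = .data$label), alpha = 0.6)
  } else {
    p <- p + ggplot2::geom_point(ggplot2::aes(size = .data$area_px), alpha = 0.6)
  }
  p +
    ggplot2::scale_size_area(max_size = 6) +
    ggplot2::labs(x = "object Pearson coefficient", y = "mean NFRET",
                  size = "area (px)", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Pseudo-color FRETc image as a ggplot
#'
#' Gain-amplified, zero-clipped FRETc rendered as a raster with a labeled
#' continuous color bar (the plot analogue of [render_fretc()], which
#' produces the raw RGB array for PNG export).
#'
#' @param fretc FRETc matrix from [compute_fretc()].
#' @param gain Display gain (default 10).
#' @param display_max Display ceiling after gain (default 4095).
#' @param colormap Palette name passed to [render_fretc()]'s LUT.
#' @return A ggplot.
#' @export
plot_fretc <- function(fretc, gain = 10, display_max = 4095, colormap = "fire") {
  stopifnot(is.matrix(fretc))
  df <- tidyr::expand_grid(row = seq_len(nrow(fretc)), col = seq_len(ncol(fretc)))
  df$value <- pmin(pmax(fretc[cbind(df$row, df$col)] * gain, 0), display_max)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse(expand = c(0, 0)) +
    ggplot2::scale_x_continuous(expand = c(0, 0)) +
    ggplot2::scale_fill_gradientn(
      colours = fretc_palette(colormap), limits = c(0, display_max),
      name = sprintf("FRETc x%g", gain)) +
    ggplot2::coord_fixed() +
    ggplot2::theme_void()
}
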