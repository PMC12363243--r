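#' Default phase colour palette
#'
#' Named colours for the six ecosystem phases of the reference diagram
#' (Soil red, Freshwater blue, Marine green, Non-marine saline pink,
#' Thermal springs gold, Deep subsurface purple); any other label is
#' assigned an evenly spaced hue.
#'
#' @param labels character vector of group keys to cover.
#' @return named character vector of colours.
#' @export
phase_palette <- function(labels) {
  fixed <- c("Terrestrial>Soil" = "#d62728",
             "Aquatic>Freshwater" = "#1f77b4",
             "Aquatic>Marine" = "#2ca02c",
             "Aquatic>Non-marine Saline and Alkaline" = "#e377c2",
             "Aquatic>Thermal springs" = "#d4af37",
             "Aquatic>Deep Subsurface" = "#9467bd")
  labels <- sort(unique(labels))
  pal <- fixed[labels]
  miss <- is.na(pal)
  if (any(miss))
    pal[miss] <- grDevices::hcl(h = seq(15, 375, length.out = sum(miss) + 1L)[
      seq_len(sum(miss))], c = 100, l = 55)
  names(pal) <- labels
  pal
}

#' Render the metagenome stability diagram
#'
#' Scatter of metagenomes at their discriminant coordinates, coloured by
#' declared ecosystem label, over the KNN phase background. With `overlay`,
#' points are recoloured by a gene's normalized abundance on a reversed
#' perceptually uniform sequential colormap (cividis) and metagenomes with
#' missing abundance are hidden from the overlay layer.
#'
#' @param coords a `stability_diagram` or coordinates data.frame.
#' @param grid optional `phase_grid` background from the same coordinates.
#' @param overlay optional overlay table from [overlay_values()].
#' @param palette named phase colours; default [phase_palette()].
#' @param file optional output path (`.svg`, `.png`, or `.pdf` by
#'   extension); rendering is deterministic given inputs.
#' @param width,height device size in inches.
#' @param point_size scatter point size.
#' @return the ggplot object, invisibly.
#' @export
render_diagram <- function(coords, grid = NULL, overlay = NULL,
                           palette = NULL, file = NULL,
                           width = 7, height = 6, point_size = 1.6) {
  coords <- .as_coords(coords)
  labs_all <- unique(c(coords$group_key,
                       if (!is.null(grid)) grid$cells$label))
  palette <- palette %||% phase_palette(labs_all)
  p <- ggplot2::ggplot()
  if (!is.null(grid)) {
    if (!all(range(coords$x) >= min(grid$x_edges)) ||
        !all(range(coords$x) <= max(grid$x_edges)))
      stop("grid does not cover the coordinate range; was it built from ",
           "these coordinates?")
    p <- p + ggplot2::geom_raster(
      data = grid$cells,
      ggplot2::aes(x = .data$x, y = .data$y, fill = .data$label),
      alpha = 0.35)
  }
  p <- p + ggplot2::scale_fill_manual(values = palette, name = "KNN phase")
  if (is.null(overlay)) {
    p <- p + ggplot2::geom_point(
      data = coords,
      ggplot2::aes(x = .data$x, y = .data$y, colour = .data$group_key),
      size = point_size) +
      ggplot2::scale_colour_manual(values = palette, name = "Ecosystem")
  } else {
    shown <- merge(coords, overlay[!overlay$hidden, , drop = FALSE],
                   by = "sample_id")
    p <- p + ggplot2::geom_point(
      data = shown,
      ggplot2::aes(x = .data$x, y = .data$y, colour = .data$abundance),
      size = point_size) +
      ggplot2::scale_colour_viridis_c(option = "cividis", direction = -1,
                                      name = "Abundance / 1e9 bases")
  }
  p <- p +
    ggplot2::labs(x = "Discriminant axis 1", y = "Discriminant axis 2") +
    ggplot2::theme_minimal()
  if (!is.null(file)) {
    ext <- tolower(tools::file_ext(file))
    dev <- switch(ext, svg = svg, png = function(f, width, height)
      png(f, width = width, height = height, units = "in", res = 150),
      pdf = grDevices::pdf,
      stop("unsupported image format: .", ext))
    dev(file, width = width, height = height)
    print(p)
    dev.off()
  }
  invisible(p)
}
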