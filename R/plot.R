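# ggplot2 views of region tables. The SVG renderer is the canonical export;
# autoplot() gives the same diagram as a ggplot object for interactive work
# and figure composition.

#' Plot a region table as a Venn diagram
#'
#' Draws the family's fixed curves with per-set fills (united sets share the
#' colour of their group's first label), set-name captions and one count per
#' (quotient) region at its anchor — the ggplot2 twin of [render_svg()].
#'
#' @param object A `venn_regions` table (plain or quotient).
#' @param layout A `venn_layout`; defaults to the shipped layout.
#' @param style A [venn_style()].
#' @param ... Unused.
#' @return A ggplot object.
#' @examples
#' fam <- venn_family(list(P = c("x", "y"), Q = c("y", "z")))
#' autoplot(venn_regions(fam))
#' @exportS3Method ggplot2::autoplot
autoplot.venn_regions <- function(object, layout = NULL,
                                  style = venn_style(), ...) {
  family <- regions_family(object)
  layout <- layout %||% venn_layout(nrow(family))
  fills <- curve_fills(family$label, regions_grouping(object), style)
  curves <- dplyr::bind_rows(lapply(family$label, function(lab) {
    poly <- layout$curves[[lab]]
    tibble(label = lab, x = poly[, 1], y = poly[, 2])
  }))
  anchors <- table_anchors(object, layout)
  anchors$count <- object$count
  names_df <- dplyr::left_join(layout$name_positions,
                               tibble(label = family$label,
                                      name = family$name),
                               by = "label")
  ggplot2::ggplot() +
    ggplot2::geom_polygon(
      data = curves,
      ggplot2::aes(x = .data$x, y = .data$y,
                   group = .data$label, fill = .data$label),
      alpha = style$opacity, colour = "#333333", linewidth = 0.4
    ) +
    ggplot2::geom_text(
      data = anchors,
      ggplot2::aes(x = .data$x, y = .data$y, label = .data$count),
      size = style$font_size / ggplot2::.pt
    ) +
    ggplot2::geom_text(
      data = names_df,
      ggplot2::aes(x = .data$x, y = .data$y, label = .data$name),
      size = style$font_size / ggplot2::.pt, fontface = "bold"
    ) +
    ggplot2::scale_fill_manual(values = fills, guide = "none") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::theme_void()
}

#' @rdname autoplot.venn_regions
#' @param table A `venn_regions` table.
#' @export
plot_venn <- function(table, layout = NULL, style = venn_style(), ...) {
  autoplot.venn_regions(table, layout = layout, style = style, ...)
}
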