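# SVG rendering. SVG is the canonical output format; the rasterizer below is
# a small deterministic companion for the package's own SVG dialect.

VENN_PALETTE <- c(
  A = "#1f77b4", B = "#ff7f0e", C = "#2ca02c",
  D = "#d62728", E = "#9467bd", F = "#8c564b"
)

#' Diagram style
#'
#' Display parameters for rendering: all pinned so output is byte
#' reproducible. Defaults: 14 pt labels, fill opacity 0.5, a fixed 6-colour
#' palette (`#1f77b4`, `#ff7f0e`, `#2ca02c`, `#d62728`, `#9467bd`,
#' `#8c564b`), 700x700 canvas.
#'
#' @param font_size Font size in pt; must be > 0.
#' @param opacity Fill opacity in `[0, 1]`.
#' @param colors Character vector of up to 6 fill colours, recycled to the
#'   labels A..F in order.
#' @param canvas Canvas edge length in SVG user units.
#' @return A `venn_style` list.
#' @export
venn_style <- function(font_size = 14, opacity = 0.5,
                       colors = VENN_PALETTE, canvas = VENN_CANVAS) {
  if (!is.numeric(font_size) || length(font_size) != 1L ||
      is.na(font_size) || font_size <= 0) {
    stop_validation("`font_size` must be a single positive number")
  }
  if (!is.numeric(opacity) || length(opacity) != 1L ||
      is.na(opacity) || opacity < 0 || opacity > 1) {
    stop_validation("`opacity` must be within [0, 1]")
  }
  if (!is.character(colors) || !length(colors)) {
    stop_validation("`colors` must be a character vector of colours")
  }
  colors <- rep_len(colors, 6L)
  names(colors) <- SET_LABELS
  structure(
    list(font_size = font_size, opacity = opacity,
         colors = colors, canvas = canvas),
    class = "venn_style"
  )
}

# fill colour per set label: members of a united group all take the colour
# of the group's alphabetically first label
curve_fills <- function(labels, grouping, style) {
  fills <- style$colors[labels]
  if (!is.null(grouping) && !grouping_is_identity(grouping)) {
    first_of_group <- vapply(grouping_groups(grouping), min, character(1))
    fills <- style$colors[first_of_group[grouping$group[
      match(labels, grouping$label)]]]
  }
  names(fills) <- labels
  fills
}

fmt_num <- function(x) sprintf("%.2f", x)

#' Render a region table as an SVG diagram
#'
#' Draws the family's fixed curves, the set-name captions and one count text
#' per (quotient) region at its anchor. The curve geometry is identical
#' across all groupings of the same family — uniting sets only changes fill
#' colours (united sets share the colour of the group's first label) and
#' which counts are drawn where.
#'
#' @param table A `venn_regions` table (plain or quotient).
#' @param layout A `venn_layout`; defaults to the shipped layout for the
#'   family's set count.
#' @param style A [venn_style()].
#' @return The SVG document as a single character string.
#' @examples
#' fam <- venn_family(list(P = "x", Q = c("x", "y")))
#' svg <- render_svg(venn_regions(fam))
#' @export
render_svg <- function(table, layout = NULL, style = venn_style()) {
  assert_regions(table)
  if (!inherits(style, "venn_style")) {
    stop_validation("`style` must be a `venn_style`")
  }
  family <- regions_family(table)
  layout <- layout %||% venn_layout(nrow(family))
  if (!inherits(layout, "venn_layout")) {
    stop_validation("`layout` must be a `venn_layout`")
  }
  if (layout$n != nrow(family)) {
    stop_validation(sprintf(
      "layout is for %d sets but the family has %d", layout$n, nrow(family)
    ))
  }
  grouping <- regions_grouping(table)
  fills <- curve_fills(family$label, grouping, style)
  anchors <- table_anchors(table, layout)

  doc <- xml2::xml_new_root(
    "svg",
    xmlns = "http://www.w3.org/2000/svg",
    width = as.character(style$canvas),
    height = as.character(style$canvas),
    viewBox = sprintf("0 0 %d %d", style$canvas, style$canvas)
  )
  g_curves <- xml2::xml_add_child(doc, "g", class = "curves")
  for (label in family$label) {
    poly <- layout$curves[[label]]
    xml2::xml_add_child(
      g_curves, "polygon",
      id = paste0("curve-", label),
      points = paste(fmt_num(poly[, 1]), fmt_num(poly[, 2]),
                     sep = ",", collapse = " "),
      fill = unname(fills[[label]]),
      `fill-opacity` = fmt_num(style$opacity),
      `fill-rule` = "evenodd",
      stroke = "#333333",
      `stroke-width` = "1"
    )
  }
  g_names <- xml2::xml_add_child(doc, "g", class = "set-names")
  for (i in seq_len(nrow(family))) {
    pos <- layout$name_positions[layout$name_positions$label ==
                                   family$label[[i]], ]
    node <- xml2::xml_add_child(
      g_names, "text", class = "set-name",
      x = fmt_num(pos$x), y = fmt_num(pos$y),
      `text-anchor` = "middle",
      `font-family` = "sans-serif",
      `font-size` = fmt_num(style$font_size)
    )
    xml2::xml_set_text(node, family$name[[i]])
  }
  g_counts <- xml2::xml_add_child(doc, "g", class = "counts")
  for (i in seq_len(nrow(table))) {
    node <- xml2::xml_add_child(
      g_counts, "text", class = "count",
      region = table$code[[i]],
      x = fmt_num(anchors$x[[i]]), y = fmt_num(anchors$y[[i]]),
      `text-anchor` = "middle",
      `font-family` = "sans-serif",
      `font-size` = fmt_num(style$font_size)
    )
    xml2::xml_set_text(node, as.character(table$count[[i]]))
  }
  as.character(doc)
}

#' Write an SVG diagram to a file
#'
#' @inheritParams render_svg
#' @param path Output file path. The write is atomic: on error no partial
#'   file is left behind.
#' @return `path`, invisibly.
#' @export
write_svg <- function(table, path, layout = NULL, style = venn_style()) {
  svg <- render_svg(table, layout = layout, style = style)
  atomic_write_lines(svg, path)
  invisible(path)
}

#' Rasterize a rendered SVG diagram to PNG
#'
#' A deterministic rasterizer for the SVG dialect emitted by [render_svg()]:
#' polygon fills are composited with their opacity over a white background
#' using the even-odd rule. Text elements (captions and counts) are not
#' rasterized — SVG is the canonical, fully faithful format and PNG export
#' is a convenience for quick previews.
#'
#' @param svg SVG document text, as returned by [render_svg()].
#' @param dpi Output resolution; the canvas's user units are taken as pixels
#'   at 96 dpi, so `dpi = 48` halves the pixel dimensions.
#' @param path Optional output file path (atomic write).
#' @return The PNG bytes as a raw vector, invisibly if `path` is given.
#' @export
rasterize_png <- function(svg, dpi = 96, path = NULL) {
  if (!is.numeric(dpi) || length(dpi) != 1L || is.na(dpi) || dpi <= 0) {
    stop_validation("`dpi` must be a single positive number")
  }
  doc <- tryCatch(xml2::read_xml(svg), error = function(e) {
    stop_venn(sprintf("cannot rasterize: malformed SVG (%s)",
                      conditionMessage(e)), "vennkit_conversion_error")
  })
  root <- xml2::xml_name(doc)
  if (root != "svg") {
    stop_venn("cannot rasterize: document root is not <svg>",
              "vennkit_conversion_error")
  }
  canvas <- suppressWarnings(as.numeric(xml2::xml_attr(doc, "width")))
  if (is.na(canvas) || canvas <= 0) {
    stop_venn("cannot rasterize: missing or invalid canvas size",
              "vennkit_conversion_error")
  }
  scale <- dpi / 96
  wpx <- max(1L, as.integer(round(canvas * scale)))
  img <- array(1, dim = c(wpx, wpx, 3))  # white background
  # pixel centers in user units
  cs <- (seq_len(wpx) - 0.5) / scale
  px <- rep(cs, times = wpx)            # x varies fastest
  py <- rep(cs, each = wpx)
  polys <- xml2::xml_find_all(doc, ".//*[local-name()='polygon']")
  for (node in polys) {
    pts <- xml2::xml_attr(node, "points")
    coords <- as.numeric(unlist(strsplit(trimws(pts), "[ ,]+")))
    if (anyNA(coords) || length(coords) < 6 || length(coords) %% 2 != 0) {
      stop_venn("cannot rasterize: invalid polygon points",
                "vennkit_conversion_error")
    }
    poly <- matrix(coords, ncol = 2, byrow = TRUE)
    fill <- xml2::xml_attr(node, "fill")
    if (is.na(fill) || fill == "none") next
    alpha <- suppressWarnings(as.numeric(xml2::xml_attr(node, "fill-opacity")))
    if (is.na(alpha)) alpha <- 1
    rgb <- tryCatch(grDevices::col2rgb(fill)[, 1] / 255, error = function(e) {
      stop_venn(sprintf("cannot rasterize: invalid fill colour '%s'", fill),
                "vennkit_conversion_error")
    })
    inside <- point_in_polygon(px, py, poly)
    if (!any(inside)) next
    mask <- matrix(inside, nrow = wpx)  # rows = x, cols = y
    for (ch in 1:3) {
      plane <- img[, , ch]
      plane[mask] <- rgb[[ch]] * alpha + plane[mask] * (1 - alpha)
      img[, , ch] <- plane
    }
  }
  # writePNG expects rows = y
  bytes <- png::writePNG(aperm(img, c(2, 1, 3)))
  if (is.null(path)) return(bytes)
  atomic_write_bin(bytes, path)
  invisible(bytes)
}
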