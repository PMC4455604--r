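# Diagram geometry. Shapes are fixed per set count — the shipped layouts are
# static vertex/anchor tables (plain text under inst/extdata/geometry/)
# generated once and validated by point-in-polygon tests: circles up to three
# sets, ellipse arrangements for four and five, and an Edwards-style
# construction (half-planes, circle, cogwheel curves) exposing all 63 regions
# for six. Coordinates are SVG user units on a 700x700 canvas, origin
# top-left, y down.

VENN_CANVAS <- 700

#' Diagram layout for an n-set Venn diagram
#'
#' Returns the shipped, fixed geometry for `n` sets: one closed polygonal
#' curve per label, one anchor point strictly inside each of the
#' \eqn{2^n - 1} regions (where its count is drawn), and one caption position
#' per set name. The shape depends only on `n`, so set unions can be
#' displayed without redrawing the diagram.
#'
#' @param n Number of sets, 1 to 6.
#' @return A `venn_layout`: list with `n`, `canvas`, `curves` (named list of
#'   two-column vertex matrices), `anchors` (tibble `code`, `x`, `y`) and
#'   `name_positions` (tibble `label`, `x`, `y`).
#' @examples
#' layout <- venn_layout(3)
#' nrow(layout$anchors)  # 7 regions
#' @export
venn_layout <- function(n) {
  if (length(n) != 1L || is.na(n) || n != as.integer(n)) {
    stop_range("`n` must be a single integer")
  }
  n <- as.integer(n)
  if (n < 1L || n > 6L) {
    stop_range(sprintf("diagrams support 1 to 6 sets, got %d", n))
  }
  key <- paste0("layout", n)
  if (!is.null(the[[key]])) return(the[[key]])
  dir <- system.file("extdata", "geometry", package = "vennkit")
  read_geom <- function(what) {
    path <- file.path(dir, sprintf("venn%d_%s.tsv", n, what))
    if (!file.exists(path)) stop_io(sprintf("missing geometry table: %s", path))
    read.delim(path, stringsAsFactors = FALSE)
  }
  curves_df <- read_geom("curves")
  anchors <- as_tibble(read_geom("anchors"))
  names_df <- as_tibble(read_geom("names"))
  curves <- lapply(split(curves_df, curves_df$label), function(d) {
    cbind(x = d$x, y = d$y)
  })
  layout <- structure(
    list(n = n, canvas = VENN_CANVAS, curves = curves[SET_LABELS[1:n]],
         anchors = anchors, name_positions = names_df),
    class = "venn_layout"
  )
  the[[key]] <- layout
  layout
}

#' @export
print.venn_layout <- function(x, ...) {
  cat(sprintf("# venn_layout: n=%d, %d curves, %d anchors, canvas %dx%d\n",
              x$n, length(x$curves), nrow(x$anchors), x$canvas, x$canvas))
  invisible(x)
}

# Even-odd ray-casting containment test, vectorized over query points.
# Points on an edge are resolved by the half-open crossing rule; anchors are
# generated with a clear margin so the distinction never matters for them.
point_in_polygon <- function(px, py, poly) {
  nv <- nrow(poly)
  xs <- poly[, 1]; ys <- poly[, 2]
  x2 <- c(xs[-1], xs[1]); y2 <- c(ys[-1], ys[1])
  inside <- rep(FALSE, length(px))
  for (i in seq_len(nv)) {
    crosses <- ((ys[i] > py) != (y2[i] > py))
    if (any(crosses)) {
      xint <- (x2[i] - xs[i]) * (py[crosses] - ys[i]) / (y2[i] - ys[i]) + xs[i]
      hit <- px[crosses] < xint
      inside[crosses] <- xor(inside[crosses], hit)
    }
  }
  inside
}

#' Classify points by the diagram region containing them
#'
#' The programmatic twin of clicking a diagram region: returns, for each
#' point, the signature code of the curves strictly containing it, or
#' `"outside"` for points inside no curve.
#'
#' @param layout A `venn_layout`.
#' @param x,y Numeric vectors of point coordinates (canvas units).
#' @return A character vector of region codes (e.g. `"AC"`) or `"outside"`.
#' @examples
#' layout <- venn_layout(2)
#' a <- layout$anchors
#' locate_point(layout, a$x, a$y)
#' @export
locate_point <- function(layout, x, y) {
  if (!inherits(layout, "venn_layout")) {
    stop_validation("`layout` must be a `venn_layout`")
  }
  stopifnot(length(x) == length(y))
  inside <- vapply(layout$curves, function(poly) point_in_polygon(x, y, poly),
                   logical(length(x)))
  inside <- matrix(inside, nrow = length(x))
  labels <- names(layout$curves)
  out <- apply(inside, 1L, function(row) paste(labels[row], collapse = ""))
  out[out == ""] <- "outside"
  out
}

#' Anchor point of a quotient region
#'
#' When sets are united the drawn curves do not move; a quotient region's
#' count is placed at the anchor of its canonical representative original
#' region — the signature containing all member labels of every included
#' group and no label of an excluded group. That region always exists in the
#' full layout.
#'
#' @param layout A `venn_layout`.
#' @param grouping A `venn_grouping` over the layout's labels.
#' @param signature Quotient signature: a character vector of group codes, or
#'   a single `"_"`-joined code string.
#' @return A named numeric vector `c(x = , y = )`.
#' @examples
#' fam <- venn_family(list(a = "1", b = "2", c = "3", d = "4", e = "5"))
#' g <- parse_union_code("BC", fam)
#' quotient_anchor(venn_layout(5), g, c("A", "BC"))
#' @export
quotient_anchor <- function(layout, grouping, signature) {
  if (!inherits(layout, "venn_layout")) {
    stop_validation("`layout` must be a `venn_layout`")
  }
  if (!is_venn_grouping(grouping)) {
    stop_validation("`grouping` must be a `venn_grouping`")
  }
  if (!setequal(grouping$label, names(layout$curves))) {
    stop_validation("grouping labels do not match the layout's curves")
  }
  codes <- grouping_codes(grouping)
  if (length(signature) == 1L && !signature %in% codes) {
    # canonical string form: "_"-joined, or concatenated single letters
    signature <- if (grepl("_", signature, fixed = TRUE)) {
      strsplit(signature, "_", fixed = TRUE)[[1]]
    } else {
      strsplit(signature, "", fixed = TRUE)[[1]]
    }
  }
  signature <- unique(as.character(signature))
  bad <- setdiff(signature, codes)
  if (!length(signature) || length(bad)) {
    stop_validation(sprintf(
      "invalid quotient signature [%s] for groups [%s]",
      paste(signature, collapse = ","), paste(codes, collapse = ",")
    ))
  }
  rep_code <- group_code(signature)  # all member labels, sorted
  row <- match(rep_code, layout$anchors$code)
  c(x = layout$anchors$x[[row]], y = layout$anchors$y[[row]])
}

# anchor coordinates for every row of a (possibly quotient) region table
table_anchors <- function(table, layout) {
  grouping <- regions_grouping(table)
  if (is.null(grouping)) {
    idx <- match(table$code, layout$anchors$code)
    tibble(code = table$code,
           x = layout$anchors$x[idx], y = layout$anchors$y[idx])
  } else {
    pts <- lapply(table$members, quotient_anchor,
                  layout = layout, grouping = grouping)
    tibble(code = table$code,
           x = vapply(pts, `[[`, numeric(1), "x"),
           y = vapply(pts, `[[`, numeric(1), "y"))
  }
}
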