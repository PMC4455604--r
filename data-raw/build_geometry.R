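# Generates the shipped diagram geometry under inst/extdata/geometry/.
# Run from the package root:  Rscript data-raw/build_geometry.R
#
# For each set count n in 1..6 this script
#   1. builds one closed polygonal curve per label (>= 64 vertices each,
#      700x700 canvas, origin top-left, y down):
#        n <= 3  circles
#        n = 4,5 classic ellipse arrangements
#        n = 6   Edwards-style construction: two half-plane rectangles, a
#                circle, and three cogwheel (star) polygons whose on/off
#                sectors realize all 63 regions
#   2. classifies a dense grid by curve membership and checks that every one
#      of the 2^n - 1 region signatures is realized with a clear interior
#      margin,
#   3. picks each region's anchor as the deepest interior grid point
#      (maximum distance to any curve boundary), locally refined,
#   4. writes curves, anchors and set-name caption positions as TSV.

CANVAS <- 700
GRID_STEP <- 2
MIN_MARGIN <- 2.5

pip <- function(px, py, poly) {
  xs <- poly[, 1]; ys <- poly[, 2]
  x2 <- c(xs[-1], xs[1]); y2 <- c(ys[-1], ys[1])
  inside <- rep(FALSE, length(px))
  for (i in seq_len(nrow(poly))) {
    cr <- (ys[i] > py) != (y2[i] > py)
    if (any(cr)) {
      xint <- (x2[i] - xs[i]) * (py[cr] - ys[i]) / (y2[i] - ys[i]) + xs[i]
      inside[cr] <- xor(inside[cr], px[cr] < xint)
    }
  }
  inside
}

# min distance from points to a polygon's boundary
dist_to_poly <- function(px, py, poly) {
  xs <- poly[, 1]; ys <- poly[, 2]
  x2 <- c(xs[-1], xs[1]); y2 <- c(ys[-1], ys[1])
  best <- rep(Inf, length(px))
  for (i in seq_len(nrow(poly))) {
    dx <- x2[i] - xs[i]; dy <- y2[i] - ys[i]
    len2 <- dx * dx + dy * dy
    t <- if (len2 == 0) rep(0, length(px)) else
      pmin(1, pmax(0, ((px - xs[i]) * dx + (py - ys[i]) * dy) / len2))
    d2 <- (px - (xs[i] + t * dx))^2 + (py - (ys[i] + t * dy))^2
    best <- pmin(best, d2)
  }
  sqrt(best)
}

circle <- function(cx, cy, r, k = 96) {
  th <- seq(0, 2 * pi, length.out = k + 1)[-(k + 1)]
  cbind(cx + r * cos(th), cy + r * sin(th))
}

ellipse <- function(cx, cy, a, b, angle_deg, k = 96) {
  th <- seq(0, 2 * pi, length.out = k + 1)[-(k + 1)]
  ang <- angle_deg * pi / 180
  x0 <- a * cos(th); y0 <- b * sin(th)
  cbind(cx + x0 * cos(ang) - y0 * sin(ang),
        cy + x0 * sin(ang) + y0 * cos(ang))
}

rectangle <- function(x1, y1, x2, y2, per_side = 17) {
  sub <- function(xa, ya, xb, yb) {
    t <- seq(0, 1, length.out = per_side + 1)[-(per_side + 1)]
    cbind(xa + t * (xb - xa), ya + t * (yb - ya))
  }
  rbind(sub(x1, y1, x2, y1), sub(x2, y1, x2, y2),
        sub(x2, y2, x1, y2), sub(x1, y2, x1, y1))
}

# cogwheel polygon: radius alternates between r_in and r_out across 32
# angular sectors according to `on`; arc_pts vertices per sector
cogwheel <- function(cx, cy, r_in, r_out, on, arc_pts = 4) {
  n_sec <- length(on)
  pts <- NULL
  for (j in seq_len(n_sec) - 1L) {
    r <- if (on[j + 1]) r_out else r_in
    th <- seq(j, j + 1, length.out = arc_pts + 1)[1:arc_pts] * 2 * pi / n_sec
    pts <- rbind(pts, cbind(cx + r * cos(th), cy + r * sin(th)))
  }
  pts
}

build_curves <- function(n) {
  labs <- LETTERS[1:n]
  curves <- switch(as.character(n),
    "1" = list(circle(350, 350, 230)),
    "2" = list(circle(255, 350, 195), circle(445, 350, 195)),
    "3" = {
      d <- 105; r <- 185; cx <- 350; cy <- 375
      list(circle(cx, cy - d, r),
           circle(cx - d * sqrt(3) / 2, cy + d / 2, r),
           circle(cx + d * sqrt(3) / 2, cy + d / 2, r))
    },
    "4" = {
      a <- 0.36 * CANVAS; b <- 0.225 * CANVAS
      list(ellipse(0.350 * CANVAS, 0.600 * CANVAS, a, b, -140),
           ellipse(0.450 * CANVAS, 0.500 * CANVAS, a, b, -140),
           ellipse(0.544 * CANVAS, 0.500 * CANVAS, a, b, -40),
           ellipse(0.644 * CANVAS, 0.600 * CANVAS, a, b, -40))
    },
    "5" = {
      a <- 0.435 * CANVAS; b <- 0.25 * CANVAS
      ps <- list(
        c(0.428, 0.449, 155), c(0.469, 0.543, 82), c(0.558, 0.523, 10),
        c(0.578, 0.432, 118), c(0.489, 0.383, 46)
      )
      lapply(ps, function(p) {
        ellipse(p[1] * CANVAS, (1 - p[2]) * CANVAS, a, b, -p[3], k = 128)
      })
    },
    "6" = {
      on <- function(f) vapply(0:31, f, logical(1))
      list(
        rectangle(30, 30, 350, 670),             # A: left half-plane
        rectangle(30, 30, 670, 350),             # B: top half-plane
        circle(350, 350, 150, k = 128),          # C
        cogwheel(350, 350, 95, 215, on(function(j) (j %% 8) < 4)),   # D
        cogwheel(350, 350, 95, 215, on(function(j) (j %% 4) < 2)),   # E
        cogwheel(350, 350, 95, 215, on(function(j) (j %% 2) < 1))    # F
      )
    }
  )
  names(curves) <- labs
  curves
}

all_codes <- function(labs) {
  n <- length(labs)
  unlist(lapply(seq_len(n), function(k) {
    apply(combn(labs, k), 2, paste, collapse = "")
  }))
}

build_layout <- function(n) {
  curves <- build_curves(n)
  labs <- names(curves)
  gs <- seq(GRID_STEP / 2, CANVAS, by = GRID_STEP)
  px <- rep(gs, times = length(gs))
  py <- rep(gs, each = length(gs))
  inside <- vapply(curves, function(poly) pip(px, py, poly),
                   logical(length(px)))
  sig <- apply(inside, 1, function(row) paste(labs[row], collapse = ""))
  codes <- all_codes(labs)
  missing <- setdiff(codes, unique(sig))
  if (length(missing)) {
    stop(sprintf("n=%d: regions not realized: %s", n,
                 paste(missing, collapse = ", ")))
  }
  anchors <- do.call(rbind, lapply(codes, function(code) {
    idx <- which(sig == code)
    if (length(idx) > 3000) idx <- idx[seq(1, length(idx), length.out = 3000)]
    d <- rep(Inf, length(idx))
    for (poly in curves) {
      d <- pmin(d, dist_to_poly(px[idx], py[idx], poly))
    }
    best <- idx[which.max(d)]
    # local refinement on a fine grid around the best coarse point
    fx <- seq(px[best] - GRID_STEP, px[best] + GRID_STEP, by = 0.25)
    fy <- seq(py[best] - GRID_STEP, py[best] + GRID_STEP, by = 0.25)
    qx <- rep(fx, times = length(fy)); qy <- rep(fy, each = length(fx))
    fin <- vapply(curves, function(poly) pip(qx, qy, poly),
                  logical(length(qx)))
    fsig <- apply(fin, 1, function(row) paste(labs[row], collapse = ""))
    keep <- which(fsig == code)
    fd <- rep(Inf, length(keep))
    for (poly in curves) {
      fd <- pmin(fd, dist_to_poly(qx[keep], qy[keep], poly))
    }
    j <- keep[which.max(fd)]
    if (max(fd) < MIN_MARGIN) {
      stop(sprintf("n=%d region %s: margin %.2f below %.2f",
                   n, code, max(fd), MIN_MARGIN))
    }
    data.frame(code = code, x = qx[j], y = qy[j], margin = max(fd))
  }))
  # caption positions: outermost curve vertex pushed outward, clamped
  centroid <- c(mean(px[sig != ""]), mean(py[sig != ""]))
  names_pos <- do.call(rbind, lapply(labs, function(lab) {
    poly <- curves[[lab]]
    d <- sqrt((poly[, 1] - centroid[1])^2 + (poly[, 2] - centroid[2])^2)
    v <- poly[which.max(d), ]
    dir <- (v - centroid) / max(d)
    p <- pmin(pmax(v + 18 * dir, 14), CANVAS - 14)
    data.frame(label = lab, x = p[1], y = p[2])
  }))
  list(curves = curves, anchors = anchors, names = names_pos)
}

out_dir <- file.path("inst", "extdata", "geometry")
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

for (n in 1:6) {
  t0 <- Sys.time()
  lay <- build_layout(n)
  curves_df <- do.call(rbind, lapply(names(lay$curves), function(lab) {
    poly <- lay$curves[[lab]]
    data.frame(label = lab, vertex = seq_len(nrow(poly)),
               x = round(poly[, 1], 3), y = round(poly[, 2], 3))
  }))
  write.table(curves_df, file.path(out_dir, sprintf("venn%d_curves.tsv", n)),
              sep = "\t", row.names = FALSE, quote = FALSE)
  anchors <- lay$anchors
  anchors$x <- round(anchors$x, 3); anchors$y <- round(anchors$y, 3)
  write.table(anchors[c("code", "x", "y")],
              file.path(out_dir, sprintf("venn%d_anchors.tsv", n)),
              sep = "\t", row.names = FALSE, quote = FALSE)
  nm <- lay$names
  nm$x <- round(nm$x, 3); nm$y <- round(nm$y, 3)
  write.table(nm, file.path(out_dir, sprintf("venn%d_names.tsv", n)),
              sep = "\t", row.names = FALSE, quote = FALSE)
  message(sprintf("n=%d ok: %d regions, min margin %.2f (%.1fs)",
                  n, nrow(anchors), min(lay$anchors$margin),
                  as.numeric(Sys.time() - t0, units = "secs")))
}

# re-verify from the rounded, shipped files
for (n in 1:6) {
  cv <- read.delim(file.path(out_dir, sprintf("venn%d_curves.tsv", n)))
  an <- read.delim(file.path(out_dir, sprintf("venn%d_anchors.tsv", n)))
  curves <- lapply(split(cv, cv$label), function(d) cbind(d$x, d$y))
  labs <- LETTERS[1:n]
  inside <- matrix(vapply(curves[labs], function(poly) pip(an$x, an$y, poly),
                          logical(nrow(an))), nrow = nrow(an))
  sig <- apply(inside, 1, function(row) paste(labs[row], collapse = ""))
  stopifnot(identical(sig, an$code))
  message(sprintf("n=%d shipped files verified", n))
}
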