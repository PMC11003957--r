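# Polygon helpers shared by the mask, tiling and biopsy-simulation modules.
#
# A "ring" is a closed polygon stored as list(x, y) without a repeated final
# vertex (the polyclip convention). A "region" is a list of rings under the
# even-odd fill rule, so Clipper output with negatively-oriented hole rings
# is representable directly. All boolean operations are delegated to
# polyclip (Clipper); shoelace areas, point-in-polygon and rasterisation are
# kept here for construction and plotting.

as_ring <- function(p) {
  if (is.list(p) && !is.null(p$x) && !is.null(p$y)) {
    ring <- list(x = as.numeric(p$x), y = as.numeric(p$y))
  } else if (is.matrix(p) || is.data.frame(p)) {
    p <- as.matrix(p)
    ring <- list(x = as.numeric(p[, 1]), y = as.numeric(p[, 2]))
  } else {
    abort("A polygon must be a list(x, y), a two-column matrix or a data frame.",
      class = "cms_geometry_error")
  }
  n <- length(ring$x)
  if (n != length(ring$y)) abort("Polygon x and y differ in length.", class = "cms_geometry_error")
  # drop an explicitly closed final vertex
  if (n > 1 && ring$x[1] == ring$x[n] && ring$y[1] == ring$y[n]) {
    ring$x <- ring$x[-n]
    ring$y <- ring$y[-n]
  }
  ring
}

#' Signed and absolute polygon area (shoelace formula)
#'
#' @param p A polygon: `list(x, y)`, a two-column matrix or a data frame.
#'   The ring need not be explicitly closed.
#' @param signed If `TRUE` return the signed area (positive for
#'   counter-clockwise rings); otherwise the absolute area.
#' @return A scalar area in squared input units.
#' @examples
#' poly_area(cbind(c(0, 100, 100, 0), c(0, 0, 100, 100))) # 10000
#' @export
poly_area <- function(p, signed = FALSE) {
  r <- as_ring(p)
  n <- length(r$x)
  if (n < 3) return(0)
  j <- c(n, seq_len(n - 1L))
  a <- 0.5 * sum(r$x[j] * r$y - r$x * r$y[j])
  if (signed) a else abs(a)
}

ring_signed_area <- function(r) {
  n <- length(r$x)
  if (n < 3) return(0)
  j <- c(n, seq_len(n - 1L))
  0.5 * sum(r$x[j] * r$y - r$x * r$y[j])
}

ring_centroid <- function(r) {
  n <- length(r$x)
  j <- c(n, seq_len(n - 1L))
  cr <- r$x[j] * r$y - r$x * r$y[j]
  a <- 0.5 * sum(cr)
  if (abs(a) < .Machine$double.eps) {
    return(c(mean(r$x), mean(r$y)))
  }
  cx <- sum((r$x[j] + r$x) * cr) / (6 * a)
  cy <- sum((r$y[j] + r$y) * cr) / (6 * a)
  c(cx, cy)
}

# force counter-clockwise orientation (positive signed area)
ring_ccw <- function(r) {
  if (ring_signed_area(r) < 0) list(x = rev(r$x), y = rev(r$y)) else r
}

rect_ring <- function(x, y, w, h = w) {
  list(x = c(x, x + w, x + w, x), y = c(y, y, y + h, y + h))
}

new_region <- function(rings) {
  structure(rings, class = "cms_region")
}

#' Build a polygonal region
#'
#' A region is a set of polygon rings under the even-odd fill rule; holes
#' are rings of opposite orientation. Regions are what the tiling and
#' biopsy-placement code intersect against.
#'
#' @param ... Polygons (each a `list(x, y)`, matrix or data frame), or a
#'   single list of polygons.
#' @return A `cms_region`.
#' @export
region <- function(...) {
  ps <- list(...)
  if (length(ps) == 1 && is.list(ps[[1]]) && is.null(ps[[1]]$x) &&
      !is.matrix(ps[[1]]) && !is.data.frame(ps[[1]])) {
    ps <- ps[[1]]
  }
  new_region(lapply(ps, function(p) ring_ccw(as_ring(p))))
}

region_empty <- function() new_region(list())

#' @export
print.cms_region <- function(x, ...) {
  cat(sprintf("<cms_region> %d ring(s), area %.4g\n", length(x), region_area(x)))
  invisible(x)
}

#' Region area
#'
#' Net enclosed area of a region (holes subtract).
#'
#' @param reg A `cms_region` (or bare list of rings).
#' @return Scalar area.
#' @export
region_area <- function(reg) {
  if (length(reg) == 0) return(0)
  sum(vapply(reg, ring_signed_area, numeric(1)))
}

region_bbox <- function(reg) {
  if (length(reg) == 0) return(c(NA_real_, NA_real_, NA_real_, NA_real_))
  xs <- unlist(lapply(reg, `[[`, "x"))
  ys <- unlist(lapply(reg, `[[`, "y"))
  c(xmin = min(xs), ymin = min(ys), xmax = max(xs), ymax = max(ys))
}

region_op <- function(a, b, op) {
  if (length(a) == 0 || (op == "intersection" && length(b) == 0)) {
    return(region_empty())
  }
  if (length(b) == 0) {
    return(new_region(unclass(a)))
  }
  out <- polyclip::polyclip(unclass(a), unclass(b), op = op,
    fillA = "evenodd", fillB = "evenodd")
  new_region(out)
}

#' Region boolean operations
#'
#' Thin wrappers over Clipper: intersection, difference and union of two
#' regions, plus the area of an intersection without materialising it.
#'
#' @param a,b `cms_region` objects.
#' @return A `cms_region`, or a scalar for `region_intersect_area()`.
#' @export
region_intersect <- function(a, b) region_op(a, b, "intersection")

#' @rdname region_intersect
#' @export
region_diff <- function(a, b) region_op(a, b, "minus")

#' @rdname region_intersect
#' @export
region_union <- function(a, b) {
  if (length(a) == 0) return(new_region(unclass(b)))
  region_op(a, b, "union")
}

#' @rdname region_intersect
#' @export
region_intersect_area <- function(a, b) region_area(region_intersect(a, b))

# rigid-motion transform of a single ring: optional mirror (x -> -x),
# rotation by `angle` radians, then translation.
transform_ring <- function(r, angle = 0, mirror = FALSE, dx = 0, dy = 0, scale = 1) {
  x <- r$x * scale
  y <- r$y * scale
  if (mirror) x <- -x
  if (angle != 0) {
    ca <- cos(angle); sa <- sin(angle)
    x2 <- ca * x - sa * y
    y2 <- sa * x + ca * y
    x <- x2; y <- y2
  }
  list(x = x + dx, y = y + dy)
}

# Even-odd point-in-region test, vectorised over points.
points_in_region <- function(px, py, reg) {
  inside <- rep(FALSE, length(px))
  for (r in reg) {
    n <- length(r$x)
    j <- c(n, seq_len(n - 1L))
    xi <- r$x; yi <- r$y
    xj <- r$x[j]; yj <- r$y[j]
    for (k in seq_len(n)) {
      crosses <- ((yi[k] > py) != (yj[k] > py)) &
        (px < (xj[k] - xi[k]) * (py - yi[k]) / (yj[k] - yi[k]) + xi[k])
      inside <- xor(inside, crosses)
    }
  }
  inside
}

# Binary raster of a region on a W x H pixel grid (pixel centres at
# (ix + 0.5, iy + 0.5), 0-based). Returns an H x W logical matrix indexed
# [row = y + 1, col = x + 1].
rasterize_region <- function(reg, width, height) {
  m <- matrix(FALSE, nrow = height, ncol = width)
  if (length(reg) == 0) return(m)
  bb <- region_bbox(reg)
  x0 <- max(0L, floor(bb["xmin"]))
  x1 <- min(width - 1L, ceiling(bb["xmax"]))
  y0 <- max(0L, floor(bb["ymin"]))
  y1 <- min(height - 1L, ceiling(bb["ymax"]))
  if (x1 < x0 || y1 < y0) return(m)
  xs <- seq.int(x0, x1) + 0.5
  ys <- seq.int(y0, y1) + 0.5
  g <- expand.grid(x = xs, y = ys)
  inside <- points_in_region(g$x, g$y, reg)
  m[seq.int(y0, y1) + 1L, seq.int(x0, x1) + 1L] <-
    t(matrix(inside, nrow = length(xs)))
  m
}

# Validate / repair one raw polygon: self-intersecting rings (which may
# have zero *signed* area, like a bowtie) are split into simple pieces;
# pieces of zero area are discarded. Returns a list of clean CCW rings,
# empty when the ring is degenerate.
clean_polygon <- function(p) {
  r <- as_ring(p)
  if (length(r$x) < 3) return(list())
  pieces <- tryCatch(
    polyclip::polysimplify(r, filltype = "evenodd"),
    error = function(e) {
      abort("Polygon could not be repaired to a simple polygon.",
        class = "cms_geometry_error", parent = e)
    }
  )
  pieces <- pieces[vapply(pieces, function(q) abs(ring_signed_area(q)) > 0, logical(1))]
  lapply(pieces, ring_ccw)
}

# Triangulate every ring of a region for fast C++ area queries. Returns a
# matrix with columns x1 y1 x2 y2 x3 y3 sign, sign -1 for hole rings.
region_triangles <- function(reg) {
  if (length(reg) == 0) return(matrix(numeric(0), ncol = 7))
  pieces <- lapply(unclass(reg), function(r) {
    tri <- cpp_triangulate(r$x, r$y)
    if (nrow(tri) == 0) return(NULL)
    cbind(tri, if (ring_signed_area(r) >= 0) 1 else -1)
  })
  do.call(rbind, Filter(Negate(is.null), pieces))
}

# attach the triangulation so repeated area queries skip re-triangulating
with_triangles <- function(reg) {
  attr(reg, "triangles") <- region_triangles(reg)
  reg
}
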