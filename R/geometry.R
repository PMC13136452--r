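# Planar polygon utilities used by every overlay operation in the package.
#
# A polygon is a numeric matrix with two columns (x, y, metres), one row per
# vertex, ring open (the first vertex is not repeated at the end). All
# operations assume a single projected, equal-area planar frame; there is no
# coordinate-reference-system handling anywhere in this package. Intersection
# is exact (Sutherland-Hodgman clipping) whenever at least one operand is
# convex, which covers every geometry this package produces: tracts and grid
# cells are axis-aligned rectangles and the study boundary is a convex hull.

#' Polygon area (shoelace formula)
#'
#' @param poly Numeric matrix with columns x, y (metres), open ring.
#' @return Area in square metres (non-negative scalar).
#' @examples
#' poly_area(rect_poly(0, 0, 3, 2)) # 6
#' @export
poly_area <- function(poly) {
  abs(poly_signed_area(poly))
}

# Signed shoelace area: positive for counter-clockwise rings.
poly_signed_area <- function(poly) {
  stopifnot(is.matrix(poly), ncol(poly) == 2)
  n <- nrow(poly)
  if (n < 3) return(0)
  x <- poly[, 1]; y <- poly[, 2]
  j <- c(2:n, 1)
  sum(x * y[j] - x[j] * y) / 2
}

#' Axis-aligned rectangle polygon
#'
#' @param x0,y0 Lower-left corner (metres).
#' @param x1,y1 Upper-right corner (metres).
#' @return A 4-vertex counter-clockwise polygon matrix.
#' @export
rect_poly <- function(x0, y0, x1, y1) {
  stopifnot(x1 > x0, y1 > y0)
  cbind(x = c(x0, x1, x1, x0), y = c(y0, y0, y1, y1))
}

poly_bbox <- function(poly) {
  c(xmin = min(poly[, 1]), ymin = min(poly[, 2]),
    xmax = max(poly[, 1]), ymax = max(poly[, 2]))
}

bbox_disjoint <- function(a, b) {
  a["xmax"] <= b["xmin"] || b["xmax"] <= a["xmin"] ||
    a["ymax"] <= b["ymin"] || b["ymax"] <= a["ymin"]
}

# Convexity test tolerating collinear vertices.
is_convex_poly <- function(poly) {
  n <- nrow(poly)
  if (n < 3) return(FALSE)
  pos <- FALSE; neg <- FALSE
  for (i in seq_len(n)) {
    p <- poly[i, ]
    q <- poly[if (i == n) 1 else i + 1, ]
    r <- poly[if (i >= n - 1) i - n + 2 else i + 2, ]
    cr <- (q[1] - p[1]) * (r[2] - q[2]) - (q[2] - p[2]) * (r[1] - q[1])
    scale <- max(abs(c(p, q, r)), 1)
    if (cr > 1e-9 * scale) pos <- TRUE
    if (cr < -1e-9 * scale) neg <- TRUE
    if (pos && neg) return(FALSE)
  }
  TRUE
}

orient_ccw <- function(poly) {
  if (poly_signed_area(poly) < 0) poly[rev(seq_len(nrow(poly))), , drop = FALSE] else poly
}

#' Convex hull of a point set
#'
#' @param pts Numeric matrix with columns x, y.
#' @return Counter-clockwise polygon matrix of the hull vertices.
#' @export
convex_hull_points <- function(pts) {
  stopifnot(is.matrix(pts), ncol(pts) == 2, nrow(pts) >= 3)
  idx <- grDevices::chull(pts)     # clockwise order
  hull <- pts[rev(idx), , drop = FALSE]
  if (nrow(hull) < 3 || poly_area(hull) <= 0) {
    stop("degenerate geometry: hull has no area")
  }
  colnames(hull) <- c("x", "y")
  hull
}

# Intersection of the segment p--q with the infinite line through a--b.
seg_line_intersect <- function(p, q, a, b) {
  d <- q - p
  e <- b - a
  denom <- e[1] * d[2] - e[2] * d[1]
  t <- (e[1] * (a[2] - p[2]) - e[2] * (a[1] - p[1])) / denom
  p + t * d
}

#' Clip a polygon by a convex polygon (Sutherland-Hodgman)
#'
#' The subject polygon may be any simple polygon; the clip polygon must be
#' convex.
#'
#' @param subject Polygon matrix (any simple polygon).
#' @param clip Convex polygon matrix.
#' @return Polygon matrix of the intersection (possibly with zero rows).
#' @export
clip_polygon <- function(subject, clip) {
  if (!is_convex_poly(clip)) {
    stop("clip polygon must be convex; neither operand of this overlay is")
  }
  clip <- orient_ccw(clip)
  out <- subject
  nc <- nrow(clip)
  for (i in seq_len(nc)) {
    if (nrow(out) < 3) return(out[0, , drop = FALSE])
    a <- clip[i, ]
    b <- clip[if (i == nc) 1 else i + 1, ]
    ex <- b[1] - a[1]; ey <- b[2] - a[2]
    inp <- out
    n <- nrow(inp)
    keep <- vector("list", 2L * n)
    k <- 0L
    prev <- inp[n, ]
    prev_in <- ex * (prev[2] - a[2]) - ey * (prev[1] - a[1]) >= 0
    for (j in seq_len(n)) {
      cur <- inp[j, ]
      cur_in <- ex * (cur[2] - a[2]) - ey * (cur[1] - a[1]) >= 0
      if (cur_in) {
        if (!prev_in) {
          k <- k + 1L; keep[[k]] <- seg_line_intersect(prev, cur, a, b)
        }
        k <- k + 1L; keep[[k]] <- cur
      } else if (prev_in) {
        k <- k + 1L; keep[[k]] <- seg_line_intersect(prev, cur, a, b)
      }
      prev <- cur
      prev_in <- cur_in
    }
    out <- if (k == 0L) subject[0, , drop = FALSE] else do.call(rbind, keep[seq_len(k)])
  }
  out
}

#' Area of intersection of two polygons
#'
#' At least one operand must be convex (always the case for the rectangles and
#' hulls this package produces).
#'
#' @param a,b Polygon matrices.
#' @return Intersection area in square metres.
#' @export
intersection_area <- function(a, b) {
  if (nrow(a) < 3 || nrow(b) < 3) return(0)
  if (bbox_disjoint(poly_bbox(a), poly_bbox(b))) return(0)
  if (is_convex_poly(b)) {
    poly_area(clip_polygon(a, b))
  } else if (is_convex_poly(a)) {
    poly_area(clip_polygon(b, a))
  } else {
    stop("intersection requires at least one convex polygon")
  }
}
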