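# Lightweight planar geometry on local metric grids.
#
# All polygons are two-column numeric matrices of vertices in metres,
# implicitly closed (first vertex is not repeated). Saltmarsh work happens on
# local projected grids at the scale of a few km, so plain Euclidean geometry
# is exact for our purposes.

#' Construct an axis-aligned rectangle polygon
#'
#' @param xmin,xmax,ymin,ymax Rectangle limits in metres.
#' @return A 4 x 2 matrix of vertices (counter-clockwise, implicitly closed).
#' @export
rect_poly <- function(xmin, xmax, ymin, ymax) {
  stopifnot(is.finite(xmin), is.finite(xmax), is.finite(ymin), is.finite(ymax),
            xmax > xmin, ymax > ymin)
  cbind(x = c(xmin, xmax, xmax, xmin), y = c(ymin, ymin, ymax, ymax))
}

#' Polygon area by the shoelace formula
#'
#' @param poly Two-column vertex matrix (implicitly closed).
#' @return Area in square metres (non-negative).
#' @export
poly_area <- function(poly) {
  if (is.null(poly) || nrow(poly) < 3) return(0)
  x <- poly[, 1]; y <- poly[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  abs(sum(x * yn - xn * y)) / 2
}

# Clip a polygon against a single half-plane a*x + b*y <= c
# (Sutherland-Hodgman step).
.clip_halfplane <- function(poly, a, b, cc) {
  n <- nrow(poly)
  if (n == 0) return(poly)
  out_x <- numeric(0); out_y <- numeric(0)
  d <- a * poly[, 1] + b * poly[, 2] - cc
  inside <- d <= 1e-12
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    if (inside[i]) {
      out_x <- c(out_x, poly[i, 1]); out_y <- c(out_y, poly[i, 2])
      if (!inside[j]) {
        t <- d[i] / (d[i] - d[j])
        out_x <- c(out_x, poly[i, 1] + t * (poly[j, 1] - poly[i, 1]))
        out_y <- c(out_y, poly[i, 2] + t * (poly[j, 2] - poly[i, 2]))
      }
    } else if (inside[j]) {
      t <- d[i] / (d[i] - d[j])
      out_x <- c(out_x, poly[i, 1] + t * (poly[j, 1] - poly[i, 1]))
      out_y <- c(out_y, poly[i, 2] + t * (poly[j, 2] - poly[i, 2]))
    }
  }
  cbind(x = out_x, y = out_y)
}

#' Clip a polygon to an axis-aligned rectangle
#'
#' Sutherland-Hodgman clipping; the clip window (a grid cell) is convex, so
#' the result is exact for simple subject polygons.
#'
#' @param poly Subject polygon (two-column matrix, implicitly closed).
#' @param xmin,xmax,ymin,ymax Clip rectangle.
#' @return Clipped polygon matrix (possibly with 0 rows).
#' @export
clip_poly_rect <- function(poly, xmin, xmax, ymin, ymax) {
  p <- poly
  p <- .clip_halfplane(p, -1, 0, -xmin)  # x >= xmin
  p <- .clip_halfplane(p,  1, 0,  xmax)  # x <= xmax
  p <- .clip_halfplane(p, 0, -1, -ymin)  # y >= ymin
  p <- .clip_halfplane(p, 0,  1,  ymax)  # y <= ymax
  p
}

#' Area of the intersection of a polygon with a rectangle
#'
#' @inheritParams clip_poly_rect
#' @return Intersection area in square metres.
#' @export
poly_rect_area <- function(poly, xmin, xmax, ymin, ymax) {
  poly_area(clip_poly_rect(poly, xmin, xmax, ymin, ymax))
}

#' Test points for inclusion in a polygon
#'
#' Even-odd (ray casting) rule; points exactly on an edge are treated as
#' inside.
#'
#' @param x,y Point coordinates (vectors of equal length).
#' @param poly Polygon matrix (implicitly closed).
#' @return Logical vector.
#' @export
points_in_poly <- function(x, y, poly) {
  px <- poly[, 1]; py <- poly[, 2]
  n <- length(px)
  inside <- rep(FALSE, length(x))
  j <- n
  for (i in seq_len(n)) {
    xi <- px[i]; yi <- py[i]; xj <- px[j]; yj <- py[j]
    crosses <- ((yi > y) != (yj > y)) &
      (x < (xj - xi) * (y - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  # edge points: distance-to-boundary check
  on_edge <- dist_to_polyline(x, y, rbind(poly, poly[1, , drop = FALSE])) < 1e-9
  inside | on_edge
}

#' Euclidean distance from points to a polyline
#'
#' Minimum distance from each point to any segment of the polyline. Grid
#' cells use their centroid; the sea wall is the canonical polyline.
#'
#' @param x,y Point coordinates.
#' @param polyline Two-column matrix of polyline vertices (>= 2 rows, open).
#' @return Numeric vector of distances in metres.
#' @export
dist_to_polyline <- function(x, y, polyline) {
  if (is.null(polyline) || nrow(polyline) < 2)
    stop("polyline must have at least 2 vertices")
  n <- nrow(polyline)
  best <- rep(Inf, length(x))
  for (i in seq_len(n - 1)) {
    ax <- polyline[i, 1]; ay <- polyline[i, 2]
    bx <- polyline[i + 1, 1]; by <- polyline[i + 1, 2]
    vx <- bx - ax; vy <- by - ay
    len2 <- vx * vx + vy * vy
    if (len2 == 0) {
      d <- sqrt((x - ax)^2 + (y - ay)^2)
    } else {
      t <- pmin(1, pmax(0, ((x - ax) * vx + (y - ay) * vy) / len2))
      d <- sqrt((x - (ax + t * vx))^2 + (y - (ay + t * vy))^2)
    }
    best <- pmin(best, d)
  }
  best
}

# Subtract axis-aligned rectangle b (xmin,xmax,ymin,ymax) from rectangle a,
# returning a list of disjoint rectangles (possibly empty) covering a \ b.
.rect_subtract1 <- function(a, b) {
  ix_min <- max(a[1], b[1]); ix_max <- min(a[2], b[2])
  iy_min <- max(a[3], b[3]); iy_max <- min(a[4], b[4])
  if (ix_min >= ix_max || iy_min >= iy_max) return(list(a))  # no overlap
  out <- list()
  if (a[1] < ix_min) out <- c(out, list(c(a[1], ix_min, a[3], a[4])))
  if (ix_max < a[2]) out <- c(out, list(c(ix_max, a[2], a[3], a[4])))
  if (a[3] < iy_min) out <- c(out, list(c(ix_min, ix_max, a[3], iy_min)))
  if (iy_max < a[4]) out <- c(out, list(c(ix_min, ix_max, iy_max, a[4])))
  out
}

#' Subtract rectangles from a rectangle
#'
#' Exact decomposition of `a` minus the union of `holes` into disjoint
#' axis-aligned rectangles. Used to carve creeks out of habitat-zone bands.
#'
#' @param a Rectangle as `c(xmin, xmax, ymin, ymax)`.
#' @param holes List of rectangles in the same format.
#' @return List of rectangles `c(xmin, xmax, ymin, ymax)`.
#' @export
rect_subtract <- function(a, holes) {
  pieces <- list(a)
  for (h in holes) {
    pieces <- unlist(lapply(pieces, .rect_subtract1, b = h), recursive = FALSE)
    if (length(pieces) == 0) break
  }
  pieces
}

# bounding box of a polygon: c(xmin, xmax, ymin, ymax)
.poly_bbox <- function(poly) {
  c(min(poly[, 1]), max(poly[, 1]), min(poly[, 2]), max(poly[, 2]))
}
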