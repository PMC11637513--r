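# Planar geometry primitives. All coordinates are meters in one projected CRS;
# bearings are degrees clockwise from north in [0, 360).

#' Bearing from one point to another
#'
#' Compass bearing (degrees clockwise from north) of the direction from
#' `(x0, y0)` towards `(x1, y1)`, in planar coordinates. Vectorised.
#'
#' @param x0,y0 Origin coordinates (m).
#' @param x1,y1 Target coordinates (m).
#' @return Numeric bearing(s) in `[0, 360)`. Coincident points give `NA`.
#' @export
bearing_to <- function(x0, y0, x1, y1) {
  dx <- x1 - x0
  dy <- y1 - y0
  b <- (atan2(dx, dy) * 180 / pi) %% 360
  b[dx == 0 & dy == 0] <- NA_real_
  b
}

#' Smallest angular difference between two bearings
#'
#' @param a,b Bearings in degrees.
#' @return Absolute circular difference in `[0, 180]`.
#' @export
angular_diff <- function(a, b) {
  d <- abs(a - b) %% 360
  pmin(d, 360 - d)
}

# Distance from points (px, py) to the segment (x0,y0)-(x1,y1).
# All arguments recycle; returns the true point-to-segment distance
# (perpendicular foot if it falls inside the segment, else nearest endpoint).
point_segment_distance <- function(px, py, x0, y0, x1, y1) {
  vx <- x1 - x0
  vy <- y1 - y0
  len2 <- vx * vx + vy * vy
  degen <- len2 == 0
  t <- ((px - x0) * vx + (py - y0) * vy) / (len2 + degen)
  t[t < 0] <- 0
  t[t > 1] <- 1
  t[degen] <- 0
  fx <- x0 + t * vx
  fy <- y0 + t * vy
  sqrt((px - fx)^2 + (py - fy)^2)
}

#' Signed area of a simple polygon (shoelace formula)
#'
#' @param poly Two-column matrix of vertices (closed or open ring).
#' @return Signed area (m^2); positive for counter-clockwise rings.
#' @export
polygon_area <- function(poly) {
  poly <- as.matrix(poly)
  n <- nrow(poly)
  if (n < 3) return(0)
  # drop an explicitly closed last vertex
  if (all(poly[1, ] == poly[n, ])) {
    poly <- poly[-n, , drop = FALSE]
    n <- n - 1
    if (n < 3) return(0)
  }
  x <- poly[, 1]; y <- poly[, 2]
  j <- c(2:n, 1)
  sum(x * y[j] - x[j] * y) / 2
}

# Clip a subject polygon against one half-plane defined by the directed clip
# edge (cx0,cy0)->(cx1,cy1); keeps the side to the left of the edge.
# Sutherland-Hodgman step.
.clip_halfplane <- function(poly, cx0, cy0, cx1, cy1) {
  n <- nrow(poly)
  if (n == 0) return(poly)
  ex <- cx1 - cx0
  ey <- cy1 - cy0
  side <- function(px, py) ex * (py - cy0) - ey * (px - cx0)
  out <- matrix(numeric(0), ncol = 2)
  s <- poly[n, ]
  s_in <- side(s[1], s[2]) >= 0
  for (i in seq_len(n)) {
    p <- poly[i, ]
    p_in <- side(p[1], p[2]) >= 0
    if (p_in) {
      if (!s_in) {
        t <- side(s[1], s[2]) / (side(s[1], s[2]) - side(p[1], p[2]))
        out <- rbind(out, s + t * (p - s))
      }
      out <- rbind(out, p)
    } else if (s_in) {
      t <- side(s[1], s[2]) / (side(s[1], s[2]) - side(p[1], p[2]))
      out <- rbind(out, s + t * (p - s))
    }
    s <- p
    s_in <- p_in
  }
  out
}

#' Clip a polygon to a convex window
#'
#' Sutherland-Hodgman clipping of a simple polygon against a convex clip
#' polygon. The clip ring may wind either way; the subject may be any simple
#' polygon.
#'
#' @param subject Two-column vertex matrix of the polygon to clip.
#' @param clip Two-column vertex matrix of a convex clip region.
#' @return Two-column vertex matrix of the clipped polygon (0 rows if empty).
#' @export
clip_polygon <- function(subject, clip) {
  subject <- as.matrix(subject)
  clip <- as.matrix(clip)
  if (polygon_area(clip) == 0) return(matrix(numeric(0), ncol = 2))
  if (polygon_area(clip) < 0) clip <- clip[rev(seq_len(nrow(clip))), , drop = FALSE]
  out <- subject
  nc <- nrow(clip)
  for (i in seq_len(nc)) {
    j <- if (i == nc) 1L else i + 1L
    out <- .clip_halfplane(out, clip[i, 1], clip[i, 2], clip[j, 1], clip[j, 2])
    if (nrow(out) == 0) break
  }
  out
}

# y-intervals covered by a simple polygon along the vertical line x = x0.
# Returns a 2-column matrix (lo, hi) of crossing-paired intervals (even-odd).
.polygon_slice <- function(poly, x0) {
  n <- nrow(poly)
  ys <- numeric(0)
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    xa <- poly[i, 1]; xb <- poly[j, 1]
    if ((xa < x0 && xb > x0) || (xa > x0 && xb < x0)) {
      t <- (x0 - xa) / (xb - xa)
      ys <- c(ys, poly[i, 2] + t * (poly[j, 2] - poly[i, 2]))
    }
  }
  if (length(ys) < 2) return(matrix(numeric(0), ncol = 2))
  ys <- sort(ys)
  matrix(ys, ncol = 2, byrow = TRUE)
}

# Total length of the union of closed intervals given as a 2-col matrix.
.union_length <- function(iv) {
  if (nrow(iv) == 0) return(0)
  o <- order(iv[, 1])
  iv <- iv[o, , drop = FALSE]
  tot <- 0
  cur_lo <- iv[1, 1]; cur_hi <- iv[1, 2]
  for (k in seq_len(nrow(iv))[-1]) {
    if (iv[k, 1] > cur_hi) {
      tot <- tot + (cur_hi - cur_lo)
      cur_lo <- iv[k, 1]; cur_hi <- iv[k, 2]
    } else {
      cur_hi <- max(cur_hi, iv[k, 2])
    }
  }
  tot + (cur_hi - cur_lo)
}

#' Area of the union of simple polygons
#'
#' Exact union area by a vertical sweep: the x-axis is cut at every vertex
#' and every pairwise edge crossing, so within each slab the union of the
#' per-polygon y-intervals has length linear in x and integrates exactly by
#' two interior evaluations. Overlaps are counted once.
#'
#' @param polys List of two-column vertex matrices (simple polygons).
#' @return Union area (m^2).
#' @export
polygon_union_area <- function(polys) {
  polys <- Filter(function(p) nrow(p) >= 3 && abs(polygon_area(p)) > 0, polys)
  if (length(polys) == 0) return(0)
  if (length(polys) == 1) return(abs(polygon_area(polys[[1]])))
  xs <- unlist(lapply(polys, function(p) p[, 1]))
  # add x of all pairwise edge intersections
  edges <- do.call(rbind, lapply(polys, function(p) {
    n <- nrow(p)
    cbind(p, p[c(2:n, 1), , drop = FALSE])
  }))
  ne <- nrow(edges)
  for (a in seq_len(ne - 1)) {
    e1 <- edges[a, ]
    d1x <- e1[3] - e1[1]; d1y <- e1[4] - e1[2]
    for (b in (a + 1):ne) {
      e2 <- edges[b, ]
      d2x <- e2[3] - e2[1]; d2y <- e2[4] - e2[2]
      den <- d1x * d2y - d1y * d2x
      if (den == 0) next
      t <- ((e2[1] - e1[1]) * d2y - (e2[2] - e1[2]) * d2x) / den
      u <- ((e2[1] - e1[1]) * d1y - (e2[2] - e1[2]) * d1x) / den
      if (t >= 0 && t <= 1 && u >= 0 && u <= 1) {
        xs <- c(xs, e1[1] + t * d1x)
      }
    }
  }
  xs <- sort(unique(xs))
  if (length(xs) < 2) return(0)
  area <- 0
  for (k in seq_len(length(xs) - 1)) {
    a <- xs[k]; b <- xs[k + 1]
    w <- b - a
    if (w <= 0) next
    x1 <- a + w / 3
    x2 <- a + 2 * w / 3
    L1 <- .union_length(do.call(rbind, lapply(polys, .polygon_slice, x0 = x1)))
    L2 <- .union_length(do.call(rbind, lapply(polys, .polygon_slice, x0 = x2)))
    area <- area + w * (L1 + L2) / 2
  }
  area
}
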