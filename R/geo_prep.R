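# Road-network preparation: high-traffic selection, 10-m segmentation, and
# proximity queries. Roads live in a plain data.frame with a list-column of
# polyline vertex matrices; segments are one flat data.frame so that distance
# and bearing queries vectorise.

#' Build a road table
#'
#' Constructs the road container used by the pipeline: one row per road with
#' the polyline vertices (a two-column matrix, planar meters) and the
#' AADT-by-year record (a named numeric vector, names = calendar years).
#'
#' @param road_id Character vector of identifiers.
#' @param polyline List of two-column vertex matrices (>= 2 vertices each).
#' @param aadt_by_year List of named numeric vectors, one per road
#'   (`c("2010" = 30000, ...)`), values in vehicles/day.
#' @return A `data.frame` of class `wm_roads` with columns `road_id`,
#'   `polyline`, `aadt_by_year`.
#' @export
roads_table <- function(road_id, polyline, aadt_by_year) {
  stopifnot(length(road_id) == length(polyline),
            length(road_id) == length(aadt_by_year))
  for (p in polyline) {
    p <- as.matrix(p)
    if (nrow(p) < 2 || ncol(p) != 2)
      stop("each polyline needs >= 2 vertices and 2 columns")
  }
  for (a in aadt_by_year) {
    if (length(a) == 0 || is.null(names(a)) || any(a < 0))
      stop("aadt_by_year entries must be named non-negative vectors")
  }
  out <- data.frame(road_id = as.character(road_id), stringsAsFactors = FALSE)
  out$polyline <- lapply(polyline, function(p) {
    m <- as.matrix(p); dimnames(m) <- NULL; storage.mode(m) <- "double"; m
  })
  out$aadt_by_year <- lapply(aadt_by_year, function(a) {
    stats::setNames(as.numeric(a), names(a))
  })
  class(out) <- c("wm_roads", "data.frame")
  out
}

# AADT for a road in `year`, carrying the nearest prior year forward when the
# requested year is absent (road classification follows year of birth, but
# inventories can lag).
.aadt_for_year <- function(aadt, year, road_id, carry_forward = TRUE) {
  yrs <- as.integer(names(aadt))
  if (year %in% yrs) return(unname(aadt[as.character(year)]))
  if (carry_forward) {
    prior <- yrs[yrs < year]
    if (length(prior)) return(unname(aadt[as.character(max(prior))]))
  }
  stop(sprintf("road '%s' has no AADT for year %d and no prior year to carry forward",
               road_id, year))
}

#' Select high-traffic roads
#'
#' Keeps roads whose annual average daily traffic in `year` meets or exceeds
#' `threshold` (inclusive: a road at exactly the threshold is retained). When
#' a road has no AADT for `year`, the nearest prior year's value is carried
#' forward; a road with no usable year is an error.
#'
#' @param roads A `wm_roads` table.
#' @param year Calendar year used for classification (year of birth).
#' @param threshold Vehicles/day cut-off (default 25000).
#' @param carry_forward Carry the nearest prior year's AADT forward when
#'   `year` is missing (default `TRUE`).
#' @return The subset of `roads` classified high-traffic.
#' @export
filter_high_traffic <- function(roads, year, threshold = 25000,
                                carry_forward = TRUE) {
  if (nrow(roads) == 0) return(roads)
  vals <- mapply(.aadt_for_year, roads$aadt_by_year, road_id = roads$road_id,
                 MoreArgs = list(year = year, carry_forward = carry_forward))
  out <- roads[vals >= threshold, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Divide roads into fixed-length segments
#'
#' Tiles each polyline, in vertex order, into segments of `segment_length`
#' meters measured along the arc; the final remainder (< `segment_length`) is
#' kept as its own segment so road ends are not lost. Segment midpoints are
#' the chord midpoints of the start/end points.
#'
#' @param roads A `wm_roads` table (typically the high-traffic subset).
#' @param segment_length Target segment length in meters (default 10).
#' @return A `data.frame` with one row per segment: `segment_id`, `road_id`,
#'   `x0`, `y0`, `x1`, `y1` (segment ends), `xm`, `ym` (midpoint), `length`.
#' @export
segment_roads <- function(roads, segment_length = 10) {
  stopifnot(segment_length > 0)
  pieces <- lapply(seq_len(nrow(roads)), function(i) {
    seg <- .segment_polyline(roads$polyline[[i]], segment_length)
    if (nrow(seg) == 0)
      stop(sprintf("road '%s' has zero-length polyline", roads$road_id[i]))
    seg$road_id <- roads$road_id[i]
    seg$segment_id <- sprintf("%s_s%04d", roads$road_id[i], seq_len(nrow(seg)))
    seg
  })
  out <- do.call(rbind, pieces)
  if (is.null(out)) {
    out <- data.frame(segment_id = character(0), road_id = character(0),
                      x0 = numeric(0), y0 = numeric(0), x1 = numeric(0),
                      y1 = numeric(0), xm = numeric(0), ym = numeric(0),
                      length = numeric(0))
  } else {
    out <- out[, c("segment_id", "road_id", "x0", "y0", "x1", "y1",
                   "xm", "ym", "length")]
    rownames(out) <- NULL
  }
  out
}

# Walk one polyline by cumulative arc length, cutting every `step` meters.
.segment_polyline <- function(poly, step) {
  poly <- as.matrix(poly)
  d <- sqrt(diff(poly[, 1])^2 + diff(poly[, 2])^2)
  total <- sum(d)
  if (total <= 0) return(data.frame())
  cuts <- seq(0, total, by = step)
  if (cuts[length(cuts)] < total - 1e-9) cuts <- c(cuts, total)
  pts <- .interp_along(poly, d, cuts)
  n <- length(cuts) - 1
  data.frame(
    x0 = pts[seq_len(n), 1], y0 = pts[seq_len(n), 2],
    x1 = pts[seq_len(n) + 1, 1], y1 = pts[seq_len(n) + 1, 2],
    xm = (pts[seq_len(n), 1] + pts[seq_len(n) + 1, 1]) / 2,
    ym = (pts[seq_len(n), 2] + pts[seq_len(n) + 1, 2]) / 2,
    length = diff(cuts)
  )
}

# Points at arc-length positions `s` along a polyline with edge lengths `d`.
.interp_along <- function(poly, d, s) {
  cum <- c(0, cumsum(d))
  idx <- findInterval(s, cum, rightmost.closed = TRUE)
  idx <- pmin(pmax(idx, 1L), length(d))
  frac <- (s - cum[idx]) / d[idx]
  frac[!is.finite(frac)] <- 0
  cbind(poly[idx, 1] + frac * (poly[idx + 1, 1] - poly[idx, 1]),
        poly[idx, 2] + frac * (poly[idx + 1, 2] - poly[idx, 2]))
}

#' Road segments within a radius of a residence
#'
#' Membership uses the segment midpoint (consistent with the radial-bearing
#' join); a segment belongs when its midpoint lies within `radius` meters of
#' the residence (inclusive). This set defines the per-residence segment
#' count used by the mean-hours-downwind summary.
#'
#' @param x,y Residence coordinates (m, same projected CRS as the segments).
#' @param segments Segment table from [segment_roads()].
#' @param radius Search radius in meters (default 500).
#' @return The subset of `segments` whose midpoints lie within `radius`.
#' @export
segments_within <- function(x, y, segments, radius = 500) {
  stopifnot(length(x) == 1, length(y) == 1)
  d <- sqrt((segments$xm - x)^2 + (segments$ym - y)^2)
  out <- segments[d <= radius, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Distance to the nearest road segment
#'
#' True point-to-segment distance (perpendicular where the foot falls within
#' the segment, otherwise to the nearest endpoint), minimised over all
#' segments. This is the regression covariate "distance to nearest road" and
#' the near-road matching distance.
#'
#' @param x,y Residence coordinates (m).
#' @param segments Non-empty segment table.
#' @return Minimum distance in meters (>= 0).
#' @export
nearest_road_distance <- function(x, y, segments) {
  if (nrow(segments) == 0) stop("empty segment set")
  min(point_segment_distance(x, y, segments$x0, segments$y0,
                             segments$x1, segments$y1))
}
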