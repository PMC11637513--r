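# Building and tree shielding: percent of the region between a residence and
# a road segment that is covered by footprint polygons. The between-region is
# the triangle spanned by the segment endpoints and the residence; it is the
# simplest region consistent with a 10-m segment and degrades gracefully to
# zero area when the three points are collinear.

#' Region between a residence and a road segment
#'
#' The triangle with vertices at the segment start, segment end and the
#' residence. Collinear configurations give a degenerate (zero-area)
#' triangle, for which shielding is defined as 0.
#'
#' @param x,y Residence coordinates (m).
#' @param segment One-row segment table (columns `x0`, `y0`, `x1`, `y1`).
#' @return Three-row vertex matrix.
#' @export
between_region <- function(x, y, segment) {
  rbind(c(segment$x0, segment$y0),
        c(segment$x1, segment$y1),
        c(x, y))
}

#' Shielding fraction between a residence and a road segment
#'
#' Percent of the between-region area occupied by footprints of the given
#' kind. Footprints are clipped to the triangle and their union area is used,
#' so overlapping footprints are never double-counted; the result lies in
#' `[0, 100]`. A degenerate between-region yields 0 with a warning.
#'
#' @param x,y Residence coordinates (m).
#' @param segment One-row segment table.
#' @param footprints List of footprints (`footprint_id`, `kind`, `polygon`),
#'   as read by [read_footprints_geojson()] or built by [gen_residences()].
#' @param kind Footprint kind to use: `"building"` or `"tree"`.
#' @return Percent covered, in `[0, 100]`.
#' @export
shielding_fraction <- function(x, y, segment, footprints, kind = "building") {
  tri <- between_region(x, y, segment)
  denom <- abs(polygon_area(tri))
  if (denom == 0) {
    warning("degenerate between-region (collinear residence and segment); shielding set to 0")
    return(0)
  }
  bb <- c(min(tri[, 1]), max(tri[, 1]), min(tri[, 2]), max(tri[, 2]))
  keep <- Filter(function(fp) {
    if (!identical(fp$kind, kind)) return(FALSE)
    p <- fp$polygon
    # cheap bounding-box rejection before clipping
    !(max(p[, 1]) < bb[1] || min(p[, 1]) > bb[2] ||
        max(p[, 2]) < bb[3] || min(p[, 2]) > bb[4])
  }, footprints)
  if (length(keep) == 0) return(0)
  clipped <- lapply(keep, function(fp) clip_polygon(as.matrix(fp$polygon), tri))
  covered <- polygon_union_area(clipped)
  100 * min(covered / denom, 1)
}

#' Shielding at the max-upwind road segment
#'
#' Evaluates building and tree shielding between a residence and its
#' max-upwind road segment (the Table-1 style `bldg_shield_max` /
#' `tree_shield_max` covariates).
#'
#' @param summary One-row exposure summary with `max_segment_id` (from
#'   [cohort_exposure()] or [downwind_summary()]).
#' @param x,y Residence coordinates (m).
#' @param segments Segment table containing the max segment.
#' @param footprints Footprint list.
#' @return Named numeric vector `c(building = %, tree = %)`.
#' @export
max_road_shielding <- function(summary, x, y, segments, footprints) {
  seg <- segments[segments$segment_id == summary$max_segment_id, , drop = FALSE]
  if (nrow(seg) != 1) stop("max_segment_id not resolved in the segment table")
  c(building = shielding_fraction(x, y, seg, footprints, "building"),
    tree = shielding_fraction(x, y, seg, footprints, "tree"))
}

#' Max-road shielding for a whole cohort
#'
#' @param exposure Cohort exposure table from [cohort_exposure()].
#' @param residences Residence table (`residence_id`, `x`, `y`).
#' @param segments Segment table.
#' @param footprints Footprint list.
#' @return `exposure` with `bldg_shield_max` and `tree_shield_max` columns.
#' @export
cohort_shielding <- function(exposure, residences, segments, footprints) {
  idx <- match(exposure$residence_id, residences$residence_id)
  bldg <- numeric(nrow(exposure))
  tree <- numeric(nrow(exposure))
  for (i in seq_len(nrow(exposure))) {
    if (is.na(exposure$max_segment_id[i])) {
      bldg[i] <- NA_real_; tree[i] <- NA_real_
      next
    }
    sh <- max_road_shielding(exposure[i, ], residences$x[idx[i]],
                             residences$y[idx[i]], segments, footprints)
    bldg[i] <- sh[["building"]]
    tree[i] <- sh[["tree"]]
  }
  exposure$bldg_shield_max <- bldg
  exposure$tree_shield_max <- tree
  exposure
}
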