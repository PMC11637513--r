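# Exposed/control assignment and geographic matching. Exposed residences are
# the top quartile of hours downwind from the max-upwind road, controls the
# bottom quartile; pairs are scored by how similar the two residences sit
# relative to the exposed member's max road and their own nearest roads, plus
# a birth-year penalty, and assembled greedily from the lowest scores.

#' Assign exposed/control groups by downwind-hours quartiles
#'
#' Residences at or above the 75th percentile of max-road downwind hours are
#' `exposed`, at or below the 25th percentile `control`, the rest
#' `unassigned`. Percentiles are linear-interpolation quantiles over the
#' full supplied cohort, with inclusive boundaries.
#'
#' @param exposure Cohort exposure table (needs `residence_id`, `max_hours`).
#' @return Data frame `residence_id`, `max_hours`, `group`.
#' @export
assign_exposure_groups <- function(exposure) {
  h <- exposure$max_hours
  stopifnot(length(h) >= 4, !anyNA(h))
  q <- stats::quantile(h, c(0.25, 0.75), type = 7, names = FALSE)
  if (q[1] == q[2]) stop("degenerate quartiles: downwind hours carry no contrast")
  group <- rep("unassigned", length(h))
  group[h >= q[2]] <- "exposed"
  group[h <= q[1]] <- "control"
  data.frame(residence_id = exposure$residence_id, max_hours = h,
             group = group, stringsAsFactors = FALSE)
}

#' Match-score components for one exposed/control pair
#'
#' Locality score: absolute difference between the two residences' distances
#' to the *exposed* member's max road segment. Near-road score: absolute
#' difference of the two own nearest-road distances. Match score adds a
#' penalty of 10 per year of birth-year difference; pairs more than
#' `year_window` years apart are ineligible outright.
#'
#' @param dist_maxee,dist_maxec Distances (m) from the exposed and the
#'   control residence to the exposed member's max road segment.
#' @param near_e,near_c Own nearest-road distances (m).
#' @param year_e,year_c Birth years.
#' @param year_window Maximum allowed birth-year difference (default 4).
#' @return List with `locality`, `near_road`, `year_penalty`, `score`,
#'   `eligible`.
#' @export
match_score <- function(dist_maxee, dist_maxec, near_e, near_c,
                        year_e, year_c, year_window = 4) {
  locality <- abs(dist_maxee - dist_maxec)
  near_road <- abs(near_e - near_c)
  dy <- abs(year_e - year_c)
  list(locality = locality,
       near_road = near_road,
       year_penalty = 10 * dy,
       score = locality + near_road + 10 * dy,
       eligible = dy <= year_window)
}

#' Distance-based inclusion criterion
#'
#' A candidate pair is includable iff both the locality score and the
#' near-road score are strictly below `threshold` meters (100 m in the main
#' analysis; 15/25/50 m in stricter sensitivity runs).
#'
#' @param locality,near_road Score components (m).
#' @param threshold Inclusion threshold (default 100).
#' @return Logical.
#' @export
passes_inclusion <- function(locality, near_road, threshold = 100) {
  locality < threshold & near_road < threshold
}

#' Score all exposed-control candidate pairs
#'
#' Vectorised cross scoring: every exposed residence against every control.
#' Distances to the exposed member's max segment use the segment midpoint;
#' nearest-road distances are the true point-to-segment minima carried in
#' the exposure table.
#'
#' @param groups Output of [assign_exposure_groups()].
#' @param exposure Cohort exposure table (`residence_id`, `max_segment_id`,
#'   `nearest_dist`).
#' @param residences Residence table (`residence_id`, `x`, `y`).
#' @param records Birth records (`residence_id`, `birth_year`).
#' @param segments Segment table resolving `max_segment_id`.
#' @param year_window Maximum birth-year difference (default 4).
#' @param threshold Inclusion threshold in meters (default 100).
#' @return `data.table` of includable, year-eligible candidates with columns
#'   `exposed_id`, `control_id`, `locality`, `near_road`, `year_penalty`,
#'   `score`.
#' @export
match_candidates <- function(groups, exposure, residences, records, segments,
                             year_window = 4, threshold = 100) {
  info <- merge(groups, exposure[, c("residence_id", "max_segment_id", "nearest_dist")],
                by = "residence_id")
  info <- merge(info, residences[, c("residence_id", "x", "y")], by = "residence_id")
  info <- merge(info, records[, c("residence_id", "birth_year")], by = "residence_id")
  ex <- info[info$group == "exposed", , drop = FALSE]
  co <- info[info$group == "control", , drop = FALSE]
  if (nrow(ex) == 0 || nrow(co) == 0) {
    return(data.table::data.table(exposed_id = character(0), control_id = character(0),
                                  locality = numeric(0), near_road = numeric(0),
                                  year_penalty = numeric(0), score = numeric(0)))
  }
  if (anyNA(ex$max_segment_id)) stop("unresolved max road segment for an exposed residence")
  sidx <- match(ex$max_segment_id, segments$segment_id)
  mx <- segments$xm[sidx]; my <- segments$ym[sidx]
  dist_ee <- sqrt((ex$x - mx)^2 + (ex$y - my)^2)

  ne <- nrow(ex); nc <- nrow(co)
  chunk <- max(1L, floor(4e6 / nc))
  out <- vector("list", ceiling(ne / chunk))
  k <- 0L
  for (s in seq(1L, ne, by = chunk)) {
    e <- min(ne, s + chunk - 1L)
    ib <- s:e
    # control-to-max-segment-midpoint distances, controls x exposed block
    dmc <- sqrt(outer(co$x, mx[ib], "-")^2 + outer(co$y, my[ib], "-")^2)
    loc <- abs(sweep(dmc, 2L, dist_ee[ib], "-"))
    nr <- abs(outer(co$nearest_dist, ex$nearest_dist[ib], "-"))
    dy <- abs(outer(co$birth_year, ex$birth_year[ib], "-"))
    ok <- which(loc < threshold & nr < threshold & dy <= year_window,
                arr.ind = TRUE)
    if (nrow(ok) == 0) next
    k <- k + 1L
    out[[k]] <- data.table::data.table(
      exposed_id = ex$residence_id[ib][ok[, 2L]],
      control_id = co$residence_id[ok[, 1L]],
      locality = loc[ok], near_road = nr[ok],
      year_penalty = 10 * dy[ok])
  }
  if (k == 0L) {
    return(data.table::data.table(exposed_id = character(0), control_id = character(0),
                                  locality = numeric(0), near_road = numeric(0),
                                  year_penalty = numeric(0), score = numeric(0)))
  }
  cand <- data.table::rbindlist(out[seq_len(k)])
  cand$score <- cand$locality + cand$near_road + cand$year_penalty
  cand
}

#' Build matched sets greedily
#'
#' Candidates are sorted by ascending match score (ties: smaller locality
#' score, then stable input order) and accepted greedily: an exposed
#' residence holds at most `max_controls` controls and, unless
#' `allow_control_reuse`, each control serves one exposed residence.
#'
#' @param candidates Candidate table from [match_candidates()] (already
#'   filtered to includable, year-eligible pairs).
#' @param max_controls Cap per exposed residence (default 4).
#' @param allow_control_reuse Allow one control in several matched sets
#'   (default `FALSE`).
#' @return Data frame of accepted pairs: `exposed_id`, `control_id`,
#'   `match_score`, `locality`, `near_road`, `year_penalty`.
#' @export
build_matches <- function(candidates, max_controls = 4,
                          allow_control_reuse = FALSE) {
  if (nrow(candidates) == 0) {
    return(data.frame(exposed_id = character(0), control_id = character(0),
                      match_score = numeric(0), locality = numeric(0),
                      near_road = numeric(0), year_penalty = numeric(0),
                      stringsAsFactors = FALSE))
  }
  o <- order(candidates$score, candidates$locality, seq_len(nrow(candidates)))
  cand <- candidates[o, ]
  eid <- factor(cand$exposed_id)
  cid <- factor(cand$control_id)
  acc <- greedy_assign_cpp(as.integer(eid), as.integer(cid),
                           nlevels(eid), nlevels(cid),
                           as.integer(max_controls), allow_control_reuse)
  res <- cand[acc, ]
  data.frame(exposed_id = res$exposed_id, control_id = res$control_id,
             match_score = res$score, locality = res$locality,
             near_road = res$near_road, year_penalty = res$year_penalty,
             stringsAsFactors = FALSE)
}

#' Descriptive balance of matched exposed vs control members
#'
#' Group means (numeric) and within-group percentages (categorical/logical)
#' for the exposure metrics, outcomes and covariates, one row per variable
#' or category level.
#'
#' @param matches Matched pairs from [build_matches()].
#' @param records Birth records keyed by `residence_id`.
#' @param exposure Cohort exposure table (adds the downwind and shielding
#'   metrics when present).
#' @return Data frame `variable`, `exposed`, `control`.
#' @export
balance_table <- function(matches, records, exposure) {
  stopifnot(nrow(matches) > 0)
  grab <- function(ids) {
    d <- records[match(ids, records$residence_id), , drop = FALSE]
    ex <- exposure[match(ids, exposure$residence_id), , drop = FALSE]
    keep <- intersect(c("pct_downwind_max", "mean_pct_downwind",
                        "bldg_shield_max", "tree_shield_max", "nearest_dist"),
                      names(ex))
    cbind(d, ex[, keep, drop = FALSE])
  }
  de <- grab(unique(matches$exposed_id))
  dc <- grab(unique(matches$control_id))
  rows <- list()
  skip <- c("residence_id", "birth_record_id", "conception_date", "birth_date")
  for (v in setdiff(names(de), skip)) {
    col_e <- de[[v]]; col_c <- dc[[v]]
    if (is.numeric(col_e)) {
      rows[[length(rows) + 1L]] <- data.frame(
        variable = v, exposed = mean(col_e, na.rm = TRUE),
        control = mean(col_c, na.rm = TRUE), stringsAsFactors = FALSE)
    } else {
      lv <- sort(unique(c(as.character(col_e), as.character(col_c))))
      for (l in lv) {
        rows[[length(rows) + 1L]] <- data.frame(
          variable = paste0(v, ": ", l),
          exposed = 100 * mean(as.character(col_e) == l, na.rm = TRUE),
          control = 100 * mean(as.character(col_c) == l, na.rm = TRUE),
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}

#' Share of matched pairs on opposite sides of the matched road
#'
#' For each accepted pair, determines the side of the exposed member's max
#' road segment (sign of the cross product with the segment direction) for
#' both members and reports the fraction of pairs on strictly opposite sides.
#'
#' @param matches Matched pairs.
#' @param exposure Cohort exposure table (for `max_segment_id`).
#' @param residences Residence table (`residence_id`, `x`, `y`).
#' @param segments Segment table.
#' @return Fraction in `[0, 1]`.
#' @export
opposite_side_share <- function(matches, exposure, residences, segments) {
  if (nrow(matches) == 0) return(NA_real_)
  seg_id <- exposure$max_segment_id[match(matches$exposed_id, exposure$residence_id)]
  s <- segments[match(seg_id, segments$segment_id), , drop = FALSE]
  side_of <- function(ids) {
    r <- residences[match(ids, residences$residence_id), , drop = FALSE]
    sign((s$x1 - s$x0) * (r$y - s$y0) - (s$y1 - s$y0) * (r$x - s$x0))
  }
  se <- side_of(matches$exposed_id)
  sc <- side_of(matches$control_id)
  mean(se * sc < 0)
}
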