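# Wind-direction exposure assessment. Hourly u/v air-motion vectors are
# converted to from-directions, accumulated over each pregnancy into a
# 360-bin radial distribution (one bin per integer degree, each hour smeared
# over a +/-15 degree window), and joined to road-segment bearings to give
# hours downwind of each 10-m segment.

#' Wind from-direction from u/v components
#'
#' Meteorological convention: `u` is the eastward and `v` the northward
#' air-motion component; the from-direction is the reverse of the motion
#' bearing, i.e. `(atan2(u, v) + 180)` degrees clockwise from north. A calm
#' hour (`u = v = 0`) has no direction and returns `NA`.
#'
#' @param u,v Wind vector components (m/s). Vectorised.
#' @return Bearings in `[0, 360)`; `NA` for calm hours.
#' @export
wind_from_direction <- function(u, v) {
  d <- (atan2(u, v) * 180 / pi + 180) %% 360
  d[u == 0 & v == 0] <- NA_real_
  d
}

#' u/v components from a from-direction and speed
#'
#' Inverse of [wind_from_direction()]: air moves towards
#' `direction + 180` degrees.
#'
#' @param direction From-direction (degrees clockwise from north).
#' @param speed Wind speed (m/s).
#' @return Data frame with `u`, `v`.
#' @export
direction_to_uv <- function(direction, speed) {
  to <- (direction + 180) * pi / 180
  data.frame(u = speed * sin(to), v = speed * cos(to))
}

#' Pregnancy window in hours
#'
#' Hourly instants from 00:00 on the conception day through 23:00 on the
#' birth day, inclusive: `24 * (days + 1)`.
#'
#' @param conception_date,birth_date `Date` (or coercible) values.
#' @return Number of hours.
#' @export
pregnancy_hours <- function(conception_date, birth_date) {
  conception_date <- as.Date(conception_date)
  birth_date <- as.Date(birth_date)
  days <- as.integer(birth_date - conception_date)
  if (any(days < 0)) stop("birth date precedes conception date")
  24L * (days + 1L)
}

# Integer bin (0..359) of a from-direction, rounded to the nearest degree.
.dir_bin <- function(direction) as.integer(round(direction)) %% 360L

# Circular +/-half window sum for a single 360-count vector.
.circ_smear <- function(raw, half) {
  n <- 360L
  out <- numeric(n)
  offs <- -half:half
  for (j in seq_len(n)) {
    out[j] <- sum(raw[((j - 1L + offs) %% n) + 1L])
  }
  out
}

#' Radial distribution of downwind hours for one pregnancy
#'
#' For every hour of the pregnancy the hourly from-direction is rounded to
#' the nearest integer degree `j*` and the 31 bins `j* - 15 ... j* + 15`
#' (mod 360, inclusive window) are each incremented, so each valid hour
#' contributes exactly `2 * half_window + 1` to the distribution. Calm and
#' missing hours contribute to no bin but still count towards the pregnancy
#' length `m`; the computation errors when the share of hours with usable
#' wind falls below `min_coverage`.
#'
#' @param conception_date,birth_date Pregnancy window (`Date`).
#' @param wind Hourly wind series (`time` POSIXct UTC, `u`, `v`).
#' @param half_window Angular half-window in degrees (default 15).
#' @param min_coverage Minimum share of pregnancy hours with usable wind
#'   (default 0.95).
#' @return An object of class `radial_distribution`: list with `counts`
#'   (360 integers, bin 0 = north), `m` (pregnancy hours), `valid_hours`,
#'   and `half_window`.
#' @export
radial_distribution <- function(conception_date, birth_date, wind,
                                half_window = 15L, min_coverage = 0.95) {
  m <- pregnancy_hours(conception_date, birth_date)
  t0 <- as.POSIXct(paste(as.Date(conception_date), "00:00:00"), tz = "UTC")
  hours <- t0 + 3600 * (seq_len(m) - 1L)
  idx <- match(as.numeric(hours), as.numeric(wind$time))
  present <- !is.na(idx)
  u <- wind$u[idx[present]]
  v <- wind$v[idx[present]]
  dir <- wind_from_direction(u, v)
  valid <- is.finite(dir)
  if (m > 0 && sum(valid) / m < min_coverage) {
    stop(sprintf("wind coverage %.1f%% below the %.0f%% completeness threshold",
                 100 * sum(valid) / m, 100 * min_coverage))
  }
  raw <- tabulate(.dir_bin(dir[valid]) + 1L, nbins = 360L)
  counts <- .circ_smear(raw, as.integer(half_window))
  structure(list(counts = as.integer(counts), m = m,
                 valid_hours = sum(valid),
                 half_window = as.integer(half_window)),
            class = "radial_distribution")
}

#' @export
print.radial_distribution <- function(x, ...) {
  cat(sprintf(
    "Radial distribution: %d pregnancy hours, %d with usable wind, +/-%d deg window\n",
    x$m, x$valid_hours, x$half_window))
  cat(sprintf("  total bin mass %d (= %d x valid hours)\n",
              sum(x$counts), 2L * x$half_window + 1L))
  invisible(x)
}

#' Hours downwind of each road segment
#'
#' Joins a radial distribution to road segments: each segment is assigned
#' the integer-degree bin of the residence-to-midpoint bearing and receives
#' that bin's hour count, i.e. the number of pregnancy hours the residence
#' was downwind of the segment (wind from-direction within the angular
#' window of the segment bearing).
#'
#' @param x,y Residence coordinates (m).
#' @param rd A `radial_distribution` for this residence.
#' @param segments The within-radius segment table for this residence.
#' @return Named numeric vector of hours (`d_li`), names = `segment_id`.
#' @export
downwind_hours <- function(x, y, rd, segments) {
  if (nrow(segments) == 0) return(stats::setNames(numeric(0), character(0)))
  b <- bearing_to(x, y, segments$xm, segments$ym)
  if (anyNA(b)) stop("segment midpoint coincides with the residence; bearing undefined")
  stats::setNames(as.numeric(rd$counts[.dir_bin(b) + 1L]), segments$segment_id)
}

#' Summarise downwind hours for one residence
#'
#' Computes the mean hours downwind over all within-radius segments (zeros
#' included), the max-upwind road segment (argmax of `d_li`, ties broken by
#' the smaller residence-to-midpoint distance, then by segment id for
#' stability), and the percent-of-pregnancy metrics.
#'
#' @param x,y Residence coordinates (m).
#' @param d Named `d_li` vector from [downwind_hours()].
#' @param segments Segment table aligned with `d` (same ids).
#' @param m Pregnancy hours (must be > 0).
#' @return A one-row `data.frame`: `n_segments`, `mean_hours`, `max_segment_id`,
#'   `max_hours`, `pct_downwind_max`, `mean_pct_downwind`.
#' @export
downwind_summary <- function(x, y, d, segments, m) {
  if (m <= 0) stop("pregnancy length m must be positive")
  if (length(d) == 0) stop("no segments within radius; residence outside cohort")
  segments <- segments[match(names(d), segments$segment_id), , drop = FALSE]
  middist <- sqrt((segments$xm - x)^2 + (segments$ym - y)^2)
  pick <- order(-d, middist, segments$segment_id)[1L]
  data.frame(
    n_segments = length(d),
    mean_hours = mean(d),
    max_segment_id = segments$segment_id[pick],
    max_hours = unname(d[pick]),
    pct_downwind_max = 100 * unname(d[pick]) / m,
    mean_pct_downwind = 100 * mean(d) / m,
    stringsAsFactors = FALSE
  )
}

# ---------------------------------------------------------------------------
# Batch path: one wind series, many residences. Uses per-bin prefix sums over
# the hourly series so each pregnancy window is two column lookups, then a
# sparse circulant multiply for the +/-15 degree smear.

# Prefix-sum structure over an hourly wind series.
.wind_prefix <- function(wind) {
  stopifnot(nrow(wind) > 0)
  tnum <- as.numeric(wind$time)
  if (nrow(wind) > 1 && any(diff(tnum) != 3600))
    stop("wind series must be contiguous hourly records")
  dir <- wind_from_direction(wind$u, wind$v)
  valid <- is.finite(dir)
  H <- nrow(wind)
  M <- matrix(0L, nrow = 360L, ncol = H)
  if (any(valid)) M[cbind(.dir_bin(dir[valid]) + 1L, which(valid))] <- 1L
  P <- matrix(0L, nrow = 360L, ncol = H + 1L)
  P[, -1L] <- t(apply(M, 1L, cumsum))
  list(t0 = tnum[1], H = H, P = P, valid_cum = c(0L, cumsum(as.integer(valid))))
}

# Hour index (1-based) of a POSIXct instant in the prefix structure.
.wind_hour_index <- function(wp, tnum) as.integer((tnum - wp$t0) / 3600) + 1L

#' Downwind exposure summaries for a cohort
#'
#' Vectorised end-to-end exposure assessment: for every residence, the
#' pregnancy radial distribution is accumulated from the shared hourly wind
#' series (sampled at one site, as for a coarse reanalysis grid cell), joined
#' to the within-`radius` road segments by integer-degree bearing, and
#' summarised into the mean/max downwind-hours metrics plus the nearest-road
#' distance covariate.
#'
#' @param residences Data frame with `residence_id`, `x`, `y`,
#'   `conception_date`, `birth_date`.
#' @param segments High-traffic segment table from [segment_roads()].
#' @param wind Contiguous hourly wind series covering every pregnancy.
#' @param radius Segment-membership radius in meters (default 500).
#' @param half_window Angular half-window in degrees (default 15).
#' @param min_coverage Minimum usable-wind share per pregnancy (default 0.95).
#' @return Data frame with one row per residence: `residence_id`,
#'   `n_segments`, `nearest_dist`, `mean_hours`, `max_segment_id`,
#'   `max_hours`, `pct_downwind_max`, `mean_pct_downwind`, `m_hours`,
#'   `valid_hours`. Residences with no segment within `radius` carry
#'   `n_segments = 0` and `NA` summaries (they fall outside the cohort).
#' @export
cohort_exposure <- function(residences, segments, wind, radius = 500,
                            half_window = 15L, min_coverage = 0.95) {
  n <- nrow(residences)
  stopifnot(n > 0, nrow(segments) > 0)
  wp <- .wind_prefix(wind)
  cd <- as.Date(residences$conception_date)
  bd <- as.Date(residences$birth_date)
  h0 <- .wind_hour_index(wp, as.numeric(as.POSIXct(paste(cd, "00:00:00"), tz = "UTC")))
  m <- 24L * (as.integer(bd - cd) + 1L)
  h1 <- h0 + m - 1L
  if (any(h0 < 1L) || any(h1 > wp$H))
    stop("wind series does not cover every pregnancy window")
  valid_hours <- wp$valid_cum[h1 + 1L] - wp$valid_cum[h0]
  low <- valid_hours / m < min_coverage
  if (any(low))
    stop(sprintf("%d residences below the %.0f%% wind-coverage threshold",
                 sum(low), 100 * min_coverage))

  raw <- wp$P[, h1 + 1L, drop = FALSE] - wp$P[, h0, drop = FALSE]
  sm <- .smear_matrix(as.integer(half_window)) %*% raw   # 360 x n

  # residence-segment pairs within radius
  pr <- .residence_segment_pairs(residences$x, residences$y, segments, radius)
  b <- bearing_to(residences$x[pr$res], residences$y[pr$res],
                  segments$xm[pr$seg], segments$ym[pr$seg])
  if (anyNA(b)) stop("segment midpoint coincides with a residence")
  d <- sm[cbind(.dir_bin(b) + 1L, pr$res)]

  dt <- data.table::data.table(res = pr$res, seg = pr$seg,
                               middist = pr$middist, d = d)
  data.table::setorder(dt, res, -d, middist, seg)
  agg <- dt[, list(n_segments = .N, mean_hours = mean(d),
                   max_seg = seg[1L], max_hours = d[1L]), by = "res"]

  # nearest point-to-segment distance: a 10-m segment's true distance is
  # within +/- half a segment length of its midpoint distance, so only
  # segments close to the per-residence midpoint minimum need exact
  # evaluation; residences with no segment in radius fall back to full scan
  halfseg <- max(segments$length) / 2
  dt[, minmid := min(middist), by = "res"]
  nd <- dt[middist <= minmid + 2 * halfseg]
  nd$exact <- point_segment_distance(residences$x[nd$res], residences$y[nd$res],
                                     segments$x0[nd$seg], segments$y0[nd$seg],
                                     segments$x1[nd$seg], segments$y1[nd$seg])
  near_agg <- nd[, list(nearest = min(exact)), by = "res"]
  nearest <- rep(NA_real_, n)
  nearest[near_agg$res] <- near_agg$nearest
  miss <- which(is.na(nearest) | nearest > radius - 2 * halfseg)
  if (length(miss))
    nearest[miss] <- .nearest_distance_batch(residences$x[miss],
                                             residences$y[miss], segments)

  out <- data.frame(residence_id = residences$residence_id,
                    n_segments = 0L, nearest_dist = nearest,
                    mean_hours = NA_real_, max_segment_id = NA_character_,
                    max_hours = NA_real_, pct_downwind_max = NA_real_,
                    mean_pct_downwind = NA_real_,
                    m_hours = m, valid_hours = valid_hours,
                    stringsAsFactors = FALSE)
  out$n_segments[agg$res] <- agg$n_segments
  out$mean_hours[agg$res] <- agg$mean_hours
  out$max_segment_id[agg$res] <- segments$segment_id[agg$max_seg]
  out$max_hours[agg$res] <- agg$max_hours
  out$pct_downwind_max[agg$res] <- 100 * agg$max_hours / m[agg$res]
  out$mean_pct_downwind[agg$res] <- 100 * agg$mean_hours / m[agg$res]
  out
}

# Sparse-ish circulant smear matrix (dense 360x360; one multiply per cohort).
.smear_matrix <- function(half) {
  n <- 360L
  K <- matrix(0, n, n)
  offs <- -half:half
  for (j in seq_len(n)) K[j, ((j - 1L + offs) %% n) + 1L] <- 1
  K
}

# All (residence, segment) pairs with midpoint distance <= radius. Segments
# and residences are bucketed on a radius-sized grid so only the 3x3 cell
# neighbourhood is scanned per residence.
.residence_segment_pairs <- function(x, y, segments, radius) {
  seg_key <- paste(floor(segments$xm / radius), floor(segments$ym / radius))
  seg_by_cell <- split(seq_len(nrow(segments)), seg_key)
  rcx <- floor(x / radius); rcy <- floor(y / radius)
  res_by_cell <- split(seq_along(x), paste(rcx, rcy))
  res <- list(); seg <- list(); middist <- list()
  k <- 0L
  for (cell in names(res_by_cell)) {
    ridx <- res_by_cell[[cell]]
    cc <- as.numeric(strsplit(cell, " ", fixed = TRUE)[[1]])
    keys <- paste(rep(cc[1] + (-1:1), each = 3), cc[2] + (-1:1))
    neigh <- unlist(seg_by_cell[keys], use.names = FALSE)
    if (length(neigh) == 0) next
    D <- sqrt(outer(segments$xm[neigh], x[ridx], "-")^2 +
                outer(segments$ym[neigh], y[ridx], "-")^2)
    hit <- which(D <= radius, arr.ind = TRUE)
    if (nrow(hit) == 0) next
    k <- k + 1L
    res[[k]] <- ridx[hit[, 2L]]
    seg[[k]] <- neigh[hit[, 1L]]
    middist[[k]] <- D[hit]
  }
  list(res = as.integer(unlist(res, use.names = FALSE)),
       seg = as.integer(unlist(seg, use.names = FALSE)),
       middist = as.numeric(unlist(middist, use.names = FALSE)))
}

# Nearest point-to-segment distance for many residences, chunked.
.nearest_distance_batch <- function(x, y, segments) {
  n <- length(x)
  ns <- nrow(segments)
  chunk <- max(1L, floor(2e7 / ns))
  out <- numeric(n)
  for (s in seq(1L, n, by = chunk)) {
    e <- min(n, s + chunk - 1L)
    idx <- s:e
    px <- rep(x[idx], each = ns)
    py <- rep(y[idx], each = ns)
    D <- point_segment_distance(px, py,
                                rep(segments$x0, length(idx)), rep(segments$y0, length(idx)),
                                rep(segments$x1, length(idx)), rep(segments$y1, length(idx)))
    out[idx] <- apply(matrix(D, nrow = ns), 2L, min)
  }
  out
}
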