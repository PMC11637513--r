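# Shared in-code fixtures: tiny deterministic geometries and wind series.

# A single straight east-west road of given length at y = 0.
straight_road <- function(length = 1000, aadt = 40000, years = 2010) {
  roads_table("roadA", list(cbind(c(0, length), c(0, 0))),
              list(stats::setNames(rep(aadt, length(years)), years)))
}

# Hourly wind series with prescribed from-directions (degrees) at speed 5.
wind_from_dirs <- function(dirs, start = "2010-01-01") {
  t0 <- as.POSIXct(paste(start, "00:00:00"), tz = "UTC")
  uv <- direction_to_uv(dirs, 5)
  data.frame(time = t0 + 3600 * (seq_along(dirs) - 1), u = uv$u, v = uv$v)
}

# Per-hour brute-force count of hours each segment is upwind, the
# independent oracle for the binned radial join: an hour counts for a
# segment iff the residence->midpoint bearing is within +/-15 deg
# (inclusive) of the hourly from-direction rounded to integer degrees.
brute_force_downwind_hours <- function(x, y, dirs, segments, half = 15) {
  bins <- round(dirs) %% 360
  vapply(seq_len(nrow(segments)), function(i) {
    b <- bearing_to(x, y, segments$xm[i], segments$ym[i])
    jb <- round(b) %% 360
    sum(angular_diff(jb, bins) <= half)
  }, numeric(1))
}

# Reference greedy matcher: plain R enumeration over candidates sorted by
# (score, locality, input order), for cross-checking the packaged matcher.
reference_greedy <- function(cand, max_controls = 4, allow_reuse = FALSE) {
  o <- order(cand$score, cand$locality, seq_len(nrow(cand)))
  cand <- cand[o, , drop = FALSE]
  taken <- integer(0)
  used <- character(0)
  keep <- logical(nrow(cand))
  cnt <- list()
  for (i in seq_len(nrow(cand))) {
    e <- cand$exposed_id[i]; c <- cand$control_id[i]
    ne <- if (is.null(cnt[[e]])) 0L else cnt[[e]]
    if (ne >= max_controls) next
    if (!allow_reuse && c %in% used) next
    cnt[[e]] <- ne + 1L
    used <- c(used, c)
    keep[i] <- TRUE
  }
  cand[keep, , drop = FALSE]
}

# Random candidate table for matcher property tests.
random_candidates <- function(n, n_exposed = 5, n_control = 5) {
  data.table::data.table(
    exposed_id = sample(sprintf("e%02d", seq_len(n_exposed)), n, replace = TRUE),
    control_id = sample(sprintf("c%02d", seq_len(n_control)), n, replace = TRUE),
    locality = round(runif(n, 0, 99), 1),
    near_road = round(runif(n, 0, 99), 1),
    year_penalty = 10 * sample(0:4, n, replace = TRUE))[
      , score := locality + near_road + year_penalty][]
}

# Minimal matched scenario for the regression engine: `n_pairs` matched
# pairs on one road, records carrying only the fields supplied in `...`.
toy_epi_data <- function(weights_exposed, weights_control, weeks = 40) {
  np <- length(weights_exposed)
  eid <- sprintf("E%02d", seq_len(np))
  cid <- sprintf("C%02d", seq_len(np))
  matches <- data.frame(exposed_id = eid, control_id = cid,
                        match_score = 0, locality = 0, near_road = 0,
                        year_penalty = 0, stringsAsFactors = FALSE)
  records <- data.frame(residence_id = c(eid, cid),
                        gestational_weeks = weeks,
                        birth_weight = c(weights_exposed, weights_control),
                        stringsAsFactors = FALSE)
  exposure <- data.frame(residence_id = c(eid, cid), nearest_dist = 120,
                         pct_downwind_max = c(rep(20, np), rep(5, np)),
                         stringsAsFactors = FALSE)
  list(matches = matches, records = records, exposure = exposure)
}

# Small full synthetic study used by several suites (cached per session).
small_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- sim_config(seed = 42, n_residences = 800L,
                        study_years = c(2012L, 2014L))
      cache <<- simulate_cohort(cfg)
    }
    cache
  }
})
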