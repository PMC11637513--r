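# Synthetic study generator: road networks with AADT, hourly von Mises winds,
# residences and building/tree footprints inside the 500-m band, and birth
# records with configurable injected downwind effects. One master seed
# determines every layer (each generator reseeds from seed + a fixed offset,
# so layers are reproducible standalone and in the full pipeline).

#' Simulation configuration
#'
#' Defaults describe the study conditions the pipeline is validated under:
#' a few multi-kilometre high-traffic roads, residences scattered 10-500 m
#' on both sides, a prevailing southerly wind of moderate persistence, term
#' birth weight centred at 3300 g (sd 450), a realistic gestational-age
#' distribution (about 8% preterm, 1.5% very preterm), and a -30 g term
#' birth-weight effect injected on the top-quartile true downwind exposure.
#'
#' @param seed Master seed (integer).
#' @param n_roads Number of roads.
#' @param road_orientation_range Range (degrees) the road-axis orientation
#'   is drawn from, measured counter-clockwise from east; the default spans
#'   all orientations so road-relative wind geometry varies across roads.
#' @param road_length Road length in meters. Each road occupies its own
#'   corridor cell (side `road_length + 2 * residence_band + 200` m) at a
#'   random orientation, so road-relative wind geometry varies across the
#'   study area.
#' @param aadt_high_share Probability a road's AADT is drawn above the
#'   25,000 vehicles/day high-traffic threshold.
#' @param aadt_high_range,aadt_low_range AADT draw ranges (vehicles/day).
#' @param n_residences Number of residences.
#' @param residence_band Maximum perpendicular offset from the road (m).
#' @param study_years Two-element year range of births.
#' @param wind_prevailing Prevailing from-direction (degrees; 160 is a
#'   south-south-easterly regime).
#' @param wind_kappa von Mises concentration of hourly from-directions
#'   around the (seasonally drifting) prevailing direction.
#' @param wind_seasonal_amplitude Annual sinusoidal swing of the prevailing
#'   from-direction (degrees); gives pregnancies starting in different
#'   seasons genuinely different wind climates, as in mid-latitude regimes.
#' @param wind_seasonal_phase Phase of the seasonal swing (radians).
#' @param wind_interannual_dir_sd Year-to-year standard deviation of the
#'   prevailing direction (degrees).
#' @param wind_interannual_kappa_sd Year-to-year log-scale standard
#'   deviation of the concentration; interannual climate variability gives
#'   pregnancies in different years genuinely different downwind ceilings.
#' @param wind_speed_shape,wind_speed_scale Gamma parameters of hourly
#'   speed (m/s).
#' @param building_density,tree_density Footprints per km^2 of road band.
#' @param effect_tbw_downwind Injected term-birth-weight effect (grams).
#' @param effect_mode `"indicator"`: the effect applies to residences in
#'   the top quartile of true max-road downwind exposure; `"linear"`: the
#'   effect is grams per 10% of pregnancy downwind of the max road.
#' @param effect_decay_length Optional e-folding distance (m) multiplying
#'   the effect by `exp(-nearest_dist / decay)`; `NULL` = homogeneous.
#' @param effect_logodds Named vector of injected log-odds increments for
#'   the gestational outcomes, names `ptb` and `vptb`.
#' @param baseline_tbw_mean,baseline_tbw_sd Term-birth-weight baseline at
#'   39 weeks (g) and residual sd.
#' @param tbw_per_week Mean birth-weight change per gestational week (g).
#' @param gestation_weights Probability weights over completed weeks 22-42.
#' @param covariate_effect_map Named list of covariate effects on birth
#'   weight (grams; see defaults).
#' @param smoking_rate Baseline maternal smoking probability.
#' @param confounding Correlate smoking with road distance (breaks naive
#'   near/far comparisons while leaving the wind instrument valid).
#' @param confounding_strength Log-odds swing of smoking across the band
#'   when `confounding = TRUE`.
#' @return A `wm_sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       n_roads = 6L,
                       road_length = 2000,
                       road_orientation_range = c(0, 180),
                       aadt_high_share = 0.8,
                       aadt_high_range = c(25000, 60000),
                       aadt_low_range = c(5000, 24000),
                       n_residences = 2000L,
                       residence_band = 500,
                       study_years = c(2007L, 2016L),
                       wind_prevailing = 160,
                       wind_kappa = 1.5,
                       wind_seasonal_amplitude = 45,
                       wind_seasonal_phase = 0,
                       wind_interannual_dir_sd = 15,
                       wind_interannual_kappa_sd = 0.35,
                       wind_speed_shape = 2,
                       wind_speed_scale = 2.2,
                       building_density = 40,
                       tree_density = 40,
                       effect_tbw_downwind = -30,
                       effect_mode = c("indicator", "linear"),
                       effect_decay_length = NULL,
                       effect_logodds = c(ptb = 0, vptb = 0),
                       baseline_tbw_mean = 3300,
                       baseline_tbw_sd = 450,
                       tbw_per_week = 130,
                       gestation_weights = NULL,
                       covariate_effect_map = NULL,
                       smoking_rate = 0.05,
                       confounding = FALSE,
                       confounding_strength = 2.5) {
  effect_mode <- match.arg(effect_mode)
  if (is.null(gestation_weights)) {
    gestation_weights <- c(
      0.0008, 0.0008, 0.0009, 0.0010, 0.0011, 0.0013, 0.0015, 0.0018,
      0.0022, 0.0035,                                    # 22-31 wk (very preterm)
      0.0050, 0.0070, 0.0100, 0.0160, 0.0300,            # 32-36 wk
      0.0800, 0.1600, 0.2700, 0.2600, 0.1100, 0.0370)    # 37-42 wk
  }
  stopifnot(length(gestation_weights) == 21, all(gestation_weights > 0))
  gestation_weights <- gestation_weights / sum(gestation_weights)
  if (is.null(covariate_effect_map)) {
    covariate_effect_map <- list(
      sex_male = 120, smoking = -180, wic = -30, foreign_born = 15,
      weight_gain_per_lb = 4, maternal_age_per_yr = 1.5,
      income = c(low = -25, middle = 0, high = 25), prenatal_none = -40)
  }
  stopifnot(seed == as.integer(seed), seed < 2^31 - 10,
            baseline_tbw_sd > 0, wind_kappa >= 0,
            wind_speed_shape > 0, wind_speed_scale > 0,
            n_residences >= 1, residence_band > 10)
  structure(list(
    seed = as.integer(seed), n_roads = as.integer(n_roads),
    road_length = road_length,
    road_orientation_range = road_orientation_range,
    aadt_high_share = aadt_high_share, aadt_high_range = aadt_high_range,
    aadt_low_range = aadt_low_range,
    n_residences = as.integer(n_residences), residence_band = residence_band,
    study_years = as.integer(study_years),
    wind_prevailing = wind_prevailing, wind_kappa = wind_kappa,
    wind_seasonal_amplitude = wind_seasonal_amplitude,
    wind_seasonal_phase = wind_seasonal_phase,
    wind_interannual_dir_sd = wind_interannual_dir_sd,
    wind_interannual_kappa_sd = wind_interannual_kappa_sd,
    wind_speed_shape = wind_speed_shape, wind_speed_scale = wind_speed_scale,
    building_density = building_density, tree_density = tree_density,
    effect_tbw_downwind = effect_tbw_downwind, effect_mode = effect_mode,
    effect_decay_length = effect_decay_length,
    effect_logodds = effect_logodds,
    baseline_tbw_mean = baseline_tbw_mean, baseline_tbw_sd = baseline_tbw_sd,
    tbw_per_week = tbw_per_week, gestation_weights = gestation_weights,
    covariate_effect_map = covariate_effect_map,
    smoking_rate = smoking_rate, confounding = confounding,
    confounding_strength = confounding_strength), class = "wm_sim_config")
}

# von Mises sampler (Best-Fisher rejection), mu in degrees, returns degrees.
.rvonmises <- function(n, mu_deg, kappa) {
  if (n == 0) return(numeric(0))
  if (kappa < 1e-9) return(stats::runif(n, 0, 360))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(0)
  while (length(out) < n) {
    m <- n - length(out)
    u1 <- stats::runif(m); u2 <- stats::runif(m); u3 <- stats::runif(m)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    ok <- (cc * (2 - cc) - u2 > 0) | (log(cc / u2) + 1 - cc >= 0)
    th <- sign(u3[ok] - 0.5) * acos(pmin(pmax(f[ok], -1), 1))
    out <- c(out, th)
  }
  (mu_deg + out[seq_len(n)] * 180 / pi) %% 360
}

#' Generate the synthetic road layer
#'
#' Gently curved near-parallel polylines (vertices every 200 m with a
#' low-amplitude sinusoidal meander), AADT drawn above the high-traffic
#' threshold with probability `aadt_high_share` and constant across the
#' study years.
#'
#' @param config A [sim_config()].
#' @return A `wm_roads` table.
#' @export
gen_roads <- function(config) {
  set.seed(config$seed + 1L)
  n <- config$n_roads
  if (n == 0) return(roads_table(character(0), list(), list()))
  ids <- sprintf("road%03d", seq_len(n))
  years <- seq(config$study_years[1], config$study_years[2])
  polys <- vector("list", n); aadts <- vector("list", n)
  # each road sits in its own corridor cell and takes a random orientation,
  # so residences across the study area differ widely in their geometry
  # relative to the prevailing wind
  cell <- config$road_length + 2 * config$residence_band + 200
  ncol_grid <- max(1L, ceiling(sqrt(n)))
  for (i in seq_len(n)) {
    s <- seq(0, config$road_length, by = 200)
    amp <- stats::runif(1, 0, 25)
    wl <- config$road_length / stats::runif(1, 1, 3)
    ph <- stats::runif(1, 0, 2 * pi)
    meander <- amp * sin(2 * pi * s / wl + ph)
    theta <- stats::runif(1, config$road_orientation_range[1],
                          config$road_orientation_range[2]) * pi / 180
    cx <- ((i - 1L) %% ncol_grid) * cell
    cy <- ((i - 1L) %/% ncol_grid) * cell
    polys[[i]] <- cbind(cx + (s - config$road_length / 2) * cos(theta) -
                          meander * sin(theta),
                        cy + (s - config$road_length / 2) * sin(theta) +
                          meander * cos(theta))
    high <- stats::runif(1) < config$aadt_high_share
    rng <- if (high) config$aadt_high_range else config$aadt_low_range
    aadts[[i]] <- stats::setNames(rep(round(stats::runif(1, rng[1], rng[2])),
                                      length(years)), years)
  }
  # a usable study area needs at least one high-traffic corridor
  if (config$aadt_high_share > 0 &&
      !any(vapply(aadts, function(a) a[[1]] >= 25000, logical(1)))) {
    rng <- config$aadt_high_range
    aadts[[1]] <- stats::setNames(rep(round(stats::runif(1, rng[1], rng[2])),
                                      length(years)), years)
  }
  roads_table(ids, polys, aadts)
}

#' Generate an hourly wind series
#'
#' From-directions are von Mises around the prevailing direction, speeds
#' gamma; emitted as u/v air-motion components on a contiguous hourly UTC
#' grid covering `[start, end]`.
#'
#' @param config A [sim_config()].
#' @param start,end `Date` bounds (inclusive; whole days).
#' @return Data frame `time`, `u`, `v`.
#' @export
gen_wind <- function(config, start, end) {
  set.seed(config$seed + 2L)
  start <- as.Date(start); end <- as.Date(end)
  stopifnot(start <= end)
  t0 <- as.POSIXct(paste(start, "00:00:00"), tz = "UTC")
  H <- 24L * (as.integer(end - start) + 1L)
  # prevailing direction drifts sinusoidally over the year around a
  # year-specific mean; persistence (kappa) also varies by year
  tt <- t0 + 3600 * (seq_len(H) - 1L)
  frac_year <- as.numeric(tt - as.POSIXct("2000-01-01", tz = "UTC")) /
    (365.25 * 86400)
  yr <- as.integer(format(tt, "%Y"))
  yrs <- sort(unique(yr))
  mu_yr <- stats::setNames(
    config$wind_prevailing +
      stats::rnorm(length(yrs), 0, config$wind_interannual_dir_sd), yrs)
  kap_yr <- stats::setNames(
    config$wind_kappa *
      exp(stats::rnorm(length(yrs), 0, config$wind_interannual_kappa_sd)), yrs)
  mu <- mu_yr[as.character(yr)] + config$wind_seasonal_amplitude *
    sin(2 * pi * frac_year + config$wind_seasonal_phase)
  dir <- numeric(H)
  for (y in yrs) {
    sel <- yr == y
    dir[sel] <- .rvonmises(sum(sel), 0, kap_yr[[as.character(y)]])
  }
  dir <- (dir + unname(mu)) %% 360
  spd <- stats::rgamma(H, shape = config$wind_speed_shape,
                       scale = config$wind_speed_scale)
  spd <- pmax(spd, 1e-3)   # keep hours well-defined (no exact calms)
  uv <- direction_to_uv(dir, spd)
  data.frame(time = t0 + 3600 * (seq_len(H) - 1L), u = uv$u, v = uv$v)
}

# Point and unit tangent at arc position s along a polyline.
.point_tangent <- function(poly, s) {
  d <- sqrt(diff(poly[, 1])^2 + diff(poly[, 2])^2)
  pt <- .interp_along(poly, d, s)
  cum <- c(0, cumsum(d))
  idx <- pmin(pmax(findInterval(s, cum, rightmost.closed = TRUE), 1L), length(d))
  tx <- (poly[idx + 1, 1] - poly[idx, 1]) / d[idx]
  ty <- (poly[idx + 1, 2] - poly[idx, 2]) / d[idx]
  list(x = pt[, 1], y = pt[, 2], tx = tx, ty = ty)
}

#' Generate residences and footprints
#'
#' Residences are placed along the high-traffic roads on both sides (10 m to
#' `residence_band` perpendicular offset, both uniform); building footprints
#' (axis-aligned rectangles) and tree canopies (octagons) are scattered over
#' the same band at the configured densities.
#'
#' @param config A [sim_config()].
#' @param roads Road layer from [gen_roads()].
#' @return List with `residences` (data frame `residence_id`, `x`, `y`,
#'   `road_id`, `side`) and `footprints` (list as in
#'   [read_footprints_geojson()]).
#' @export
gen_residences <- function(config, roads) {
  set.seed(config$seed + 3L)
  ht <- filter_high_traffic(roads, config$study_years[1])
  if (nrow(ht) == 0) stop("no high-traffic roads to place residences along")
  lens <- vapply(ht$polyline, function(p)
    sum(sqrt(diff(p[, 1])^2 + diff(p[, 2])^2)), numeric(1))
  place <- function(n) {
    ridx <- sample.int(nrow(ht), n, replace = TRUE, prob = lens)
    s <- stats::runif(n) * lens[ridx]
    side <- sample(c(-1, 1), n, replace = TRUE)
    off <- stats::runif(n, 10, config$residence_band)
    out <- data.frame(ridx = ridx, x = NA_real_, y = NA_real_, side = side)
    for (r in unique(ridx)) {
      w <- which(ridx == r)
      pt <- .point_tangent(ht$polyline[[r]], s[w])
      out$x[w] <- pt$x - side[w] * off[w] * pt$ty
      out$y[w] <- pt$y + side[w] * off[w] * pt$tx
    }
    out
  }
  res <- place(config$n_residences)
  residences <- data.frame(
    residence_id = sprintf("res%06d", seq_len(config$n_residences)),
    x = res$x, y = res$y, road_id = ht$road_id[res$ridx], side = res$side,
    stringsAsFactors = FALSE)

  band_km2 <- sum(lens) * 2 * config$residence_band / 1e6
  nb <- round(config$building_density * band_km2)
  nt <- round(config$tree_density * band_km2)
  fp <- vector("list", nb + nt)
  if (nb + nt > 0) {
    ctr <- place(nb + nt)
    for (i in seq_len(nb)) {
      w <- stats::runif(1, 8, 16) / 2; h <- stats::runif(1, 6, 12) / 2
      fp[[i]] <- list(footprint_id = sprintf("bld%05d", i), kind = "building",
                      polygon = cbind(ctr$x[i] + c(-w, w, w, -w),
                                      ctr$y[i] + c(-h, -h, h, h)))
    }
    for (i in seq_len(nt)) {
      j <- nb + i
      rad <- stats::runif(1, 2, 6)
      ang <- seq(0, 2 * pi, length.out = 9)[-9]
      fp[[j]] <- list(footprint_id = sprintf("tree%05d", i), kind = "tree",
                      polygon = cbind(ctr$x[j] + rad * cos(ang),
                                      ctr$y[j] + rad * sin(ang)))
    }
  }
  list(residences = residences, footprints = fp)
}

# Lower-triangular cumulative operator for inverse-CDF gestation draws.
.gest_weeks_from_u <- function(u, W) {
  # W: n x 21 per-person weights; u: n uniforms. Returns completed weeks.
  CW <- W %*% upper.tri(matrix(0, 21, 21), diag = TRUE)
  CW <- CW / CW[, 21]
  22L + rowSums(CW < u)
}

#' Generate pregnancy skeletons
#'
#' Draws, per residence, the birth date (uniform over the study years), the
#' baseline gestational length (inverse-CDF draw from the configured weekly
#' weights, retaining the uniform so effects can re-draw weeks coherently),
#' the conception date (`birth - 7 x weeks` days), and the exposure-
#' independent covariates. Covariates have, by construction, no dependence
#' on which side of the road a residence sits: the wind instrument is valid.
#'
#' @param config A [sim_config()].
#' @param residences Residence table from [gen_residences()].
#' @return Data frame of pregnancy records (one per residence).
#' @export
gen_pregnancies <- function(config, residences) {
  set.seed(config$seed + 4L)
  n <- nrow(residences)
  d0 <- as.Date(sprintf("%d-01-01", config$study_years[1]))
  d1 <- as.Date(sprintf("%d-12-31", config$study_years[2]))
  birth_date <- d0 + sample.int(as.integer(d1 - d0) + 1L, n, replace = TRUE) - 1L
  u_gest <- stats::runif(n)
  W <- matrix(config$gestation_weights, n, 21, byrow = TRUE)
  weeks <- .gest_weeks_from_u(u_gest, W)
  conception <- birth_date - 7L * weeks
  data.frame(
    residence_id = residences$residence_id,
    birth_record_id = sub("^res", "b", residences$residence_id),
    birth_date = birth_date,
    conception_date = conception,
    birth_year = as.integer(format(birth_date, "%Y")),
    birth_month = as.integer(format(birth_date, "%m")),
    gestational_weeks = weeks,
    u_gest = u_gest,
    sex = sample(c("male", "female"), n, replace = TRUE, prob = c(0.512, 0.488)),
    maternal_age = round(pmin(pmax(stats::rnorm(n, 28, 5.5), 15), 45), 1),
    county = residences$road_id,   # one county per road corridor
    race_ethnicity = sample(c("white", "black", "hispanic", "asian", "other"),
                            n, replace = TRUE,
                            prob = c(0.35, 0.12, 0.40, 0.05, 0.08)),
    foreign_born = stats::runif(n) < 0.33,
    payment_source = sample(c("medicaid", "private", "self-pay", "other"),
                            n, replace = TRUE, prob = c(0.50, 0.30, 0.12, 0.08)),
    wic = stats::runif(n) < 0.45,
    weight_gain = round(pmin(pmax(stats::rnorm(n, 30, 10), 0), 80), 1),
    prenatal_care_month = sample(0:9, n, replace = TRUE,
                                 prob = c(0.03, 0.20, 0.30, 0.20, 0.10,
                                          0.07, 0.04, 0.03, 0.02, 0.01)),
    income_tertile = sample(c("low", "middle", "high"), n, replace = TRUE),
    education_level = sample(c("less than high school", "high school",
                               "bachelor", "postgraduate"),
                             n, replace = TRUE, prob = c(0.12, 0.45, 0.33, 0.10)),
    stringsAsFactors = FALSE)
}

#' Generate birth outcomes with injected downwind effects
#'
#' Applies the configured effects to the true computed exposure: the term
#' birth-weight effect enters the mean of the normal birth-weight draw
#' (indicator mode: residences in the top quartile of max-road downwind
#' exposure; linear mode: grams per 10% downwind; optionally scaled by
#' `exp(-nearest_dist / decay)`), and the preterm/very-preterm log-odds
#' increments shift the gestational-age category via a logistic adjustment
#' of the baseline category probabilities, re-drawing the week from the same
#' retained uniform so a zero effect reproduces the baseline draw exactly.
#' Smoking is drawn here because under the confounding switch it depends on
#' road distance (never on wind side). The grams actually added per record
#' are returned in `true_tbw_effect` so simulation truth is recoverable.
#'
#' @param config A [sim_config()].
#' @param pregnancies Pregnancy table from [gen_pregnancies()].
#' @param exposure Cohort exposure table from [cohort_exposure()] (true
#'   exposure; the generator injects effects on it).
#' @return Birth-record data frame (pregnancies plus `smoking`,
#'   `gestational_weeks` possibly re-drawn, updated `conception_date`,
#'   `birth_weight`, `true_tbw_effect`).
#' @export
gen_births <- function(config, pregnancies, exposure) {
  set.seed(config$seed + 5L)
  n <- nrow(pregnancies)
  eidx <- match(pregnancies$residence_id, exposure$residence_id)
  pct <- exposure$pct_downwind_max[eidx]
  hrs <- exposure$max_hours[eidx]
  ndist <- exposure$nearest_dist[eidx]
  decay <- if (is.null(config$effect_decay_length)) rep(1, n)
           else exp(-ndist / config$effect_decay_length)
  decay[is.na(decay)] <- 1

  term0 <- pregnancies$gestational_weeks >= 37
  # birth-weight dose: quartile of max-road downwind hours over the term
  # cohort (the contrast the matched TBW analysis estimates); gestational
  # dose: quartile of percent downwind, which is free of the mechanical
  # dependence of absolute hours on pregnancy duration
  dose_term <- .exposure_dose(config, hrs, pct, subset_for_quartile = term0,
                              measure = "hours")
  dose_all <- .exposure_dose(config, hrs, pct,
                             subset_for_quartile = rep(TRUE, n),
                             measure = "pct")

  rec <- pregnancies
  lo <- config$effect_logodds
  if (any(lo != 0)) {
    gw <- config$gestation_weights
    p_v0 <- sum(gw[1:10]); p_p0 <- sum(gw[1:15])
    x <- dose_all * decay
    p_p1 <- stats::plogis(stats::qlogis(p_p0) + .lo_get(lo, "ptb") * x)
    p_v1 <- stats::plogis(stats::qlogis(p_v0) + .lo_get(lo, "vptb") * x)
    p_v1 <- pmin(p_v1, p_p1 * 0.999)
    W <- matrix(gw, n, 21, byrow = TRUE)
    W[, 1:10] <- W[, 1:10] * (p_v1 / p_v0)
    W[, 11:15] <- W[, 11:15] * ((p_p1 - p_v1) / (p_p0 - p_v0))
    W[, 16:21] <- W[, 16:21] * ((1 - p_p1) / (1 - p_p0))
    rec$gestational_weeks <- .gest_weeks_from_u(pregnancies$u_gest, W)
    rec$conception_date <- rec$birth_date - 7L * rec$gestational_weeks
  }

  # smoking: distance-dependent only under the confounding switch
  if (config$confounding) {
    frac <- 1 - pmin(ifelse(is.na(ndist), config$residence_band, ndist),
                     config$residence_band) / config$residence_band
    p_smoke <- stats::plogis(stats::qlogis(config$smoking_rate) +
                               config$confounding_strength * (frac - 0.5))
  } else {
    p_smoke <- rep(config$smoking_rate, n)
  }
  rec$smoking <- stats::runif(n) < p_smoke

  cem <- config$covariate_effect_map
  mu <- config$baseline_tbw_mean +
    config$tbw_per_week * (rec$gestational_weeks - 39) +
    cem$sex_male * (rec$sex == "male") +
    cem$smoking * rec$smoking +
    cem$wic * rec$wic +
    cem$foreign_born * rec$foreign_born +
    cem$weight_gain_per_lb * (rec$weight_gain - 30) +
    cem$maternal_age_per_yr * (rec$maternal_age - 28) +
    unname(cem$income[rec$income_tertile]) +
    cem$prenatal_none * (rec$prenatal_care_month == 0)
  true_eff <- config$effect_tbw_downwind * dose_term * decay
  rec$birth_weight <- round(pmax(
    stats::rnorm(n, mu + true_eff, config$baseline_tbw_sd), 250))
  rec$true_tbw_effect <- true_eff
  rec$u_gest <- NULL
  rec
}

.lo_get <- function(lo, nm) if (nm %in% names(lo)) unname(lo[[nm]]) else 0

# Exposure dose for effect injection: indicator mode marks the top quartile
# of max-road downwind hours (quartile computed over `subset_for_quartile`,
# e.g. the term cohort for the birth-weight effect); linear mode is percent
# downwind per 10%.
.exposure_dose <- function(config, hrs, pct, subset_for_quartile,
                           measure = c("hours", "pct")) {
  measure <- match.arg(measure)
  if (config$effect_mode == "linear") {
    dose <- pct / 10
    dose[is.na(dose)] <- 0
    return(dose)
  }
  v <- if (measure == "hours") hrs else pct
  pool <- v[subset_for_quartile & !is.na(v)]
  if (length(pool) < 4) return(rep(0, length(v)))
  thr <- stats::quantile(pool, 0.75, type = 7, names = FALSE)
  as.numeric(!is.na(v) & v >= thr)
}

#' Simulate a complete synthetic study
#'
#' Runs every generator and the exposure assessment in order under the
#' master seed: roads, high-traffic segmentation, residences and
#' footprints, pregnancy skeletons, an hourly wind series covering every
#' possible window, true exposure via [cohort_exposure()], and finally
#' birth records with the injected effects. When an injected log-odds
#' effect re-draws gestational weeks, exposure is recomputed for the
#' affected windows so the returned table is the true exposure of the final
#' records.
#'
#' @param config A [sim_config()].
#' @return A `wm_cohort` list: `config`, `roads`, `segments`, `residences`,
#'   `footprints`, `wind`, `records`, `exposure`.
#' @export
simulate_cohort <- function(config) {
  roads <- gen_roads(config)
  ht <- filter_high_traffic(roads, config$study_years[1])
  segments <- segment_roads(ht, 10)
  rb <- gen_residences(config, roads)
  preg <- gen_pregnancies(config, rb$residences)
  start <- min(preg$birth_date) - 42L * 7L
  end <- max(preg$birth_date)
  wind <- gen_wind(config, start, end)
  resw <- cbind(rb$residences[, c("residence_id", "x", "y")],
                preg[, c("conception_date", "birth_date")])
  exposure <- cohort_exposure(resw, segments, wind)
  records <- gen_births(config, preg, exposure)
  changed <- records$gestational_weeks != preg$gestational_weeks
  if (any(changed)) {
    resw2 <- resw[changed, , drop = FALSE]
    resw2$conception_date <- records$conception_date[changed]
    exposure[match(resw2$residence_id, exposure$residence_id), ] <-
      cohort_exposure(resw2, segments, wind)
  }
  structure(list(config = config, roads = roads, segments = segments,
                 residences = rb$residences, footprints = rb$footprints,
                 wind = wind, records = records, exposure = exposure),
            class = "wm_cohort")
}

#' @export
print.wm_cohort <- function(x, ...) {
  cat(sprintf("Synthetic cohort: %d residences along %d high-traffic road(s), %d segments\n",
              nrow(x$residences), length(unique(x$segments$road_id)),
              nrow(x$segments)))
  cat(sprintf("  births %s to %s; wind %d hourly records\n",
              min(x$records$birth_date), max(x$records$birth_date),
              nrow(x$wind)))
  invisible(x)
}
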