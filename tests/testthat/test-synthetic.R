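test_that("one master seed reproduces every layer exactly", {
  cfg <- sim_config(seed = 99, n_residences = 150L, study_years = c(2013L, 2014L))
  s1 <- simulate_cohort(cfg)
  s2 <- simulate_cohort(cfg)
  expect_identical(s1$records, s2$records)
  expect_identical(s1$exposure, s2$exposure)
  expect_identical(s1$wind, s2$wind)
  expect_identical(s1$residences, s2$residences)

  # GeoJSON bytes are reproducible too
  f1 <- tempfile(fileext = ".geojson"); f2 <- tempfile(fileext = ".geojson")
  write_roads_geojson(gen_roads(cfg), f1)
  write_roads_geojson(gen_roads(cfg), f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("road AADT mix respects the configured high-traffic share", {
  cfg <- sim_config(seed = 5, n_roads = 200L, aadt_high_share = 0.7)
  roads <- gen_roads(cfg)
  share <- mean(vapply(roads$aadt_by_year, function(a) a[[1]] >= 25000,
                       logical(1)))
  expect_lt(abs(share - 0.7), 3 * sqrt(0.7 * 0.3 / 200))
  expect_equal(nrow(gen_roads(sim_config(seed = 5, n_roads = 0L))), 0)
})

test_that("wind directions follow the configured von Mises regime", {
  cfg <- sim_config(seed = 2, wind_prevailing = 200, wind_kappa = 1e7,
                    wind_seasonal_amplitude = 0, wind_interannual_dir_sd = 0)
  w <- gen_wind(cfg, "2010-01-01", "2010-01-10")
  dirs <- wind_from_direction(w$u, w$v)
  expect_lt(max(angular_diff(dirs, 200)), 1)   # kappa -> infinity limit

  cfg0 <- sim_config(seed = 2, wind_kappa = 0)
  w0 <- gen_wind(cfg0, "2010-01-01", "2011-03-01")
  d0 <- wind_from_direction(w0$u, w0$v) * pi / 180
  # circular-uniform: mean resultant length below the n = 10,000 Rayleigh
  # 1% critical value (sqrt(-log(0.01)/n) ~ 0.0215)
  n <- length(d0)
  expect_gte(n, 10000)
  R <- sqrt(mean(cos(d0))^2 + mean(sin(d0))^2)
  expect_lt(R, sqrt(-log(0.01) / n))

  # u/v round trip recovers the sampled direction
  uv <- direction_to_uv(123.456, 7)
  expect_equal(wind_from_direction(uv$u, uv$v), 123.456, tolerance = 1e-9)
})

test_that("residences stay in the band, off the road, and on both sides", {
  cfg <- sim_config(seed = 6, n_residences = 1200L)
  roads <- gen_roads(cfg)
  rb <- gen_residences(cfg, roads)
  segs <- segment_roads(filter_high_traffic(roads, 2007))
  d <- vapply(seq_len(nrow(rb$residences)), function(i)
    nearest_road_distance(rb$residences$x[i], rb$residences$y[i], segs),
    numeric(1))
  expect_true(all(d <= cfg$residence_band + 1e-6))
  expect_true(all(d >= 5))   # no residence inside a 5-m road buffer
  side_share <- mean(rb$residences$side > 0)
  expect_lt(abs(side_share - 0.5), 3 * sqrt(0.25 / 1200))
})

test_that("null effects leave exposed and control outcomes exchangeable", {
  cfg <- sim_config(seed = 13, n_residences = 1500L, effect_tbw_downwind = 0,
                    study_years = c(2012L, 2014L))
  sim <- simulate_cohort(cfg)
  expect_true(all(sim$records$true_tbw_effect == 0))
  res <- run_matched_analysis(sim, "tbw", "base")
  expect_true(res$estimate$converged)
  # within gestational-week strata the raw group outcome means coincide
  # (estimator calibration over replicates is covered by the null-rate test)
  dat <- build_analysis_data(res$matches, restrict_records(sim$records, "tbw"),
                             sim$exposure, outcome_definition("tbw"))
  w40 <- dat[dat$gestational_weeks == 40, ]
  tt <- t.test(w40$birth_weight[w40$exposed == 1],
               w40$birth_weight[w40$exposed == 0])
  expect_gt(tt$p.value, 0.001)
})

test_that("birth weights and gestation tallies match the configured model", {
  cfg <- sim_config(seed = 14, n_residences = 4000L, effect_tbw_downwind = 0,
                    study_years = c(2013L, 2014L))
  sim <- simulate_cohort(cfg)
  rec <- sim$records
  term <- rec[rec$gestational_weeks >= 37 & rec$gestational_weeks <= 42, ]
  # mean TBW at 39 weeks close to baseline after covariate effects (which
  # are approximately mean-zero except small shifts)
  m39 <- mean(term$birth_weight[term$gestational_weeks == 39])
  expect_lt(abs(m39 - cfg$baseline_tbw_mean) , 3 * cfg$baseline_tbw_sd / sqrt(200) + 60)

  # preterm prevalence matches the gestation weights
  p_ptb <- sum(cfg$gestation_weights[1:15])
  obs <- mean(rec$gestational_weeks < 37)
  expect_lt(abs(obs - p_ptb), 3 * sqrt(p_ptb * (1 - p_ptb) / nrow(rec)))
  p_v <- sum(cfg$gestation_weights[1:10])
  expect_lt(abs(mean(rec$gestational_weeks < 32) - p_v),
            3 * sqrt(p_v * (1 - p_v) / nrow(rec)) + 0.002)
})

test_that("wind side is uncorrelated with every covariate (instrument validity)", {
  cfg <- sim_config(seed = 15, n_residences = 3000L, study_years = c(2013L, 2014L))
  sim <- simulate_cohort(cfg)
  side <- sim$residences$side
  rec <- sim$records[match(sim$residences$residence_id, sim$records$residence_id), ]
  n <- length(side)
  lim <- 3 / sqrt(n)
  expect_lt(abs(cor(side, rec$maternal_age)), lim)
  expect_lt(abs(cor(side, rec$weight_gain)), lim)
  expect_lt(abs(cor(side, as.numeric(rec$smoking))), lim)
  expect_lt(abs(cor(side, as.numeric(rec$wic))), lim)
  expect_lt(abs(cor(side, as.numeric(rec$foreign_born))), lim)
  expect_lt(abs(cor(side, as.numeric(rec$race_ethnicity == "black"))), lim)
  expect_lt(abs(cor(side, as.numeric(rec$income_tertile == "low"))), lim)
})

test_that("injected preterm log-odds shift gestational categories coherently", {
  base <- sim_config(seed = 16, n_residences = 6000L, study_years = c(2013L, 2014L),
                     effect_logodds = c(ptb = 0, vptb = 0))
  bump <- sim_config(seed = 16, n_residences = 6000L, study_years = c(2013L, 2014L),
                     effect_logodds = c(ptb = 0.8, vptb = 0.8))
  s0 <- simulate_cohort(base)
  s1 <- simulate_cohort(bump)
  pct <- s0$exposure$pct_downwind_max
  top <- pct >= quantile(pct, 0.75, na.rm = TRUE)
  ptb0 <- tapply(s0$records$gestational_weeks < 37, top, mean)
  ptb1 <- tapply(s1$records$gestational_weeks < 37, top, mean)
  # zero effect reproduces the baseline draw exactly
  expect_identical(s0$records$gestational_weeks,
                   simulate_cohort(base)$records$gestational_weeks)
  # the injected log-odds raise preterm risk in the top exposure quartile
  expect_gt(ptb1[["TRUE"]], ptb0[["TRUE"]] + 0.02)
  expect_lt(abs(ptb1[["FALSE"]] - ptb0[["FALSE"]]), 0.02)
  # records are internally consistent: conception matches redrawn weeks
  expect_equal(as.integer(s1$records$birth_date - s1$records$conception_date),
               7L * s1$records$gestational_weeks)
})

test_that("YAML round trip preserves the configuration", {
  skip_if_not_installed("yaml")
  cfg <- sim_config(seed = 77, n_residences = 500L)
  f <- tempfile(fileext = ".yaml")
  yaml::write_yaml(unclass(cfg)[c("seed", "n_residences", "wind_kappa")], f)
  back <- yaml::yaml.load_file(f)
  expect_equal(back$seed, 77)
  expect_equal(back$n_residences, 500)
})
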