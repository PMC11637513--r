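test_that("from-direction follows the meteorological convention", {
  expect_equal(wind_from_direction(0, -1), 0)    # air moving south = wind from north
  expect_equal(wind_from_direction(-1, 0), 90)   # air moving west = wind from east
  expect_equal(wind_from_direction(1, 1), 225)
  expect_true(is.na(wind_from_direction(0, 0)))

  # round trip through u/v recovers the direction
  dirs <- seq(0, 359.5, by = 0.5)
  uv <- direction_to_uv(dirs, 3)
  expect_equal(wind_from_direction(uv$u, uv$v), dirs, tolerance = 1e-9)
})

test_that("pregnancy hours run from conception 0:00 through birth-day 23:00", {
  expect_equal(pregnancy_hours("2010-05-01", "2010-05-01"), 24)
  expect_equal(pregnancy_hours("2010-05-01", "2010-05-02"), 48)
  # 280-day gestation: 281 calendar days inclusive
  expect_equal(pregnancy_hours(as.Date("2010-01-01"),
                               as.Date("2010-01-01") + 280), 6744)
  expect_error(pregnancy_hours("2010-05-02", "2010-05-01"), "precedes")
})

test_that("one hour of wind marks a 31-degree inclusive window", {
  wind <- wind_from_dirs(90)
  rd <- radial_distribution("2010-01-01", "2010-01-01", wind, min_coverage = 0)
  expect_equal(rd$m, 24)
  expect_equal(rd$valid_hours, 1)
  expect_equal(sum(rd$counts), 31)
  hit <- which(rd$counts == 1) - 1          # bins are 0-indexed
  expect_equal(hit, 75:105)
})

test_that("calm hours count toward pregnancy length but no bin", {
  wind <- wind_from_dirs(rep(0, 48))
  wind$u[1:46] <- 0; wind$v[1:46] <- 0      # 46 calm hours, 2 from north
  rd <- radial_distribution("2010-01-01", "2010-01-02", wind, min_coverage = 0)
  expect_equal(rd$m, 48)
  expect_equal(rd$valid_hours, 2)
  expect_equal(sum(rd$counts), 62)
  expect_error(radial_distribution("2010-01-01", "2010-01-02", wind,
                                   min_coverage = 0.95),
               "coverage")
})

test_that("bin mass is conserved at 31 hours per valid hour", {
  set.seed(5)
  for (k in 1:10) {
    nh <- 24 * sample(1:20, 1)
    wind <- wind_from_dirs(runif(nh, 0, 360))
    rd <- radial_distribution("2010-01-01", as.Date("2010-01-01") + nh / 24 - 1,
                              wind)
    expect_equal(sum(rd$counts), 31 * rd$valid_hours)
  }
})

test_that("segment join equals the per-hour angular test", {
  segs <- segment_roads(straight_road(400), 10)
  x <- 200; y <- 150
  within <- segments_within(x, y, segs, 500)

  dirs <- round(runif(300, 0, 359))          # integer-degree from-directions
  set.seed(9)
  wind <- wind_from_dirs(dirs)
  rd <- radial_distribution("2010-01-01", as.Date("2010-01-01") + 300 / 24,
                            wind, min_coverage = 0)
  d <- downwind_hours(x, y, rd, within)
  expect_equal(unname(d), brute_force_downwind_hours(x, y, dirs, within))

  # window boundary: 20 degrees off never counts, exactly 15 always does
  seg_north <- data.frame(segment_id = "n", road_id = "r", x0 = -5, y0 = 100,
                          x1 = 5, y1 = 100, xm = 0, ym = 100, length = 10)
  rd20 <- radial_distribution("2010-01-01", "2010-01-05",
                              wind_from_dirs(rep(20, 120)), min_coverage = 0)
  expect_equal(unname(downwind_hours(0, 0, rd20, seg_north)), 0)
  rd15 <- radial_distribution("2010-01-01", "2010-01-05",
                              wind_from_dirs(rep(15, 120)), min_coverage = 0)
  expect_equal(unname(downwind_hours(0, 0, rd15, seg_north)), 120)
})

test_that("the radial join is rotation-equivariant", {
  set.seed(31)
  dirs <- runif(200, 0, 360)
  rot <- 137
  mk_segs <- function(bearings, dist = 200) {
    th <- bearings * pi / 180
    data.frame(segment_id = sprintf("s%d", seq_along(bearings)), road_id = "r",
               x0 = dist * sin(th) - 5, y0 = dist * cos(th),
               x1 = dist * sin(th) + 5, y1 = dist * cos(th),
               xm = dist * sin(th), ym = dist * cos(th), length = 10)
  }
  bearings <- runif(20, 0, 360)
  rd1 <- radial_distribution("2010-01-01", "2010-01-09",
                             wind_from_dirs(round(dirs)), min_coverage = 0)
  rd2 <- radial_distribution("2010-01-01", "2010-01-09",
                             wind_from_dirs(round((dirs + rot) %% 360)),
                             min_coverage = 0)
  d1 <- downwind_hours(0, 0, rd1, mk_segs(round(bearings) %% 360))
  d2 <- downwind_hours(0, 0, rd2, mk_segs(round((bearings + rot)) %% 360))
  expect_equal(unname(d1), unname(d2))
})

test_that("mirrored residences swap downwind percentages under wind reversal", {
  segs <- segment_roads(straight_road(1000), 10)
  set.seed(17)
  dirs <- runif(400, 0, 360)
  mk <- function(d) radial_distribution("2010-01-01", "2010-01-17",
                                        wind_from_dirs(d), min_coverage = 0)
  rdA <- mk(dirs); rdB <- mk((dirs + 180) %% 360)
  within_n <- segments_within(500, 120, segs, 500)
  within_s <- segments_within(500, -120, segs, 500)
  m <- 24 * 17
  dA_n <- downwind_hours(500, 120, rdA, within_n)
  dB_s <- downwind_hours(500, -120, rdB, within_s)
  sA <- downwind_summary(500, 120, dA_n, within_n, m)
  sB <- downwind_summary(500, -120, dB_s, within_s, m)
  expect_equal(sA$pct_downwind_max, sB$pct_downwind_max)
  expect_equal(sA$mean_hours, sB$mean_hours)
})

test_that("summaries compute mean, max, tie-break and percentages", {
  segs <- data.frame(segment_id = c("a", "b", "c"), road_id = "r",
                     x0 = 0, y0 = c(40, 60, 80), x1 = 10, y1 = c(40, 60, 80),
                     xm = 5, ym = c(40, 60, 80), length = 10)
  d <- stats::setNames(c(10, 20, 30), c("a", "b", "c"))
  s <- downwind_summary(5, 0, d, segs, 100)
  expect_equal(s$mean_hours, 20)
  expect_equal(s$max_hours, 30)
  expect_equal(s$max_segment_id, "c")
  expect_equal(s$pct_downwind_max, 30)

  # tie at the max: nearer midpoint wins
  d2 <- stats::setNames(c(30, 30, 5), c("a", "b", "c"))
  expect_equal(downwind_summary(5, 0, d2, segs, 100)$max_segment_id, "a")

  # all-zero hours: nearest segment is still the max road
  d0 <- stats::setNames(c(0, 0, 0), c("a", "b", "c"))
  s0 <- downwind_summary(5, 0, d0, segs, 100)
  expect_equal(s0$max_segment_id, "a")
  expect_equal(s0$pct_downwind_max, 0)
  expect_error(downwind_summary(5, 0, d, segs, 0), "positive")
})

test_that("the batch cohort path agrees with the per-residence path", {
  segs <- segment_roads(straight_road(600), 10)
  set.seed(3)
  dirs <- runif(24 * 40, 0, 360)
  wind <- wind_from_dirs(dirs)
  res <- data.frame(residence_id = c("r1", "r2", "r3"),
                    x = c(100, 300, 550), y = c(80, -200, 420),
                    conception_date = as.Date(c("2010-01-02", "2010-01-05", "2010-01-03")),
                    birth_date = as.Date(c("2010-01-30", "2010-02-01", "2010-01-28")))
  batch <- cohort_exposure(res, segs, wind)
  for (i in 1:3) {
    rd <- radial_distribution(res$conception_date[i], res$birth_date[i], wind)
    within <- segments_within(res$x[i], res$y[i], segs, 500)
    d <- downwind_hours(res$x[i], res$y[i], rd, within)
    s <- downwind_summary(res$x[i], res$y[i], d, within,
                          pregnancy_hours(res$conception_date[i], res$birth_date[i]))
    expect_equal(batch$mean_hours[i], s$mean_hours)
    expect_equal(batch$max_hours[i], s$max_hours)
    expect_equal(batch$max_segment_id[i], s$max_segment_id)
    expect_equal(batch$pct_downwind_max[i], s$pct_downwind_max)
    expect_equal(batch$nearest_dist[i],
                 nearest_road_distance(res$x[i], res$y[i], segs))
  }
})
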