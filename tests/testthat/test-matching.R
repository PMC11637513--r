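test_that("exposure groups are the top and bottom quartiles, inclusive", {
  expo <- data.frame(residence_id = sprintf("r%d", 1:8), max_hours = 1:8)
  g <- assign_exposure_groups(expo)
  # type-7 quantiles of 1..8: q25 = 2.75, q75 = 6.25
  expect_setequal(g$residence_id[g$group == "exposed"], c("r7", "r8"))
  expect_setequal(g$residence_id[g$group == "control"], c("r1", "r2"))

  # a residence exactly at the 75th percentile is exposed
  expo2 <- data.frame(residence_id = sprintf("r%d", 1:5), max_hours = c(0, 1, 2, 3, 4))
  g2 <- assign_exposure_groups(expo2)   # q75 = 3, q25 = 1
  expect_true("r4" %in% g2$residence_id[g2$group == "exposed"])
  expect_true("r2" %in% g2$residence_id[g2$group == "control"])

  expect_error(assign_exposure_groups(
    data.frame(residence_id = letters[1:6], max_hours = rep(7, 6))), "degenerate")
})

test_that("match score components follow the locality/near-road/year arithmetic", {
  s <- match_score(120, 150, 40, 70, 2010, 2012)
  expect_equal(s$locality, 30)
  expect_equal(s$near_road, 30)
  expect_equal(s$year_penalty, 20)
  expect_equal(s$score, 80)
  expect_true(s$eligible)
  expect_false(match_score(0, 0, 0, 0, 2010, 2015)$eligible)  # |dy| = 5 > 4
  # symmetry of the absolute-difference components
  expect_equal(match_score(150, 120, 70, 40, 2012, 2010)$score, 80)
})

test_that("inclusion is a strict-inequality test on both components", {
  expect_true(passes_inclusion(99.9, 50))
  expect_false(passes_inclusion(100, 0))
  expect_false(passes_inclusion(0, 100))
  expect_true(passes_inclusion(0, 0))
  expect_false(passes_inclusion(30, 30, threshold = 25))
})

test_that("greedy assembly matches the reference matcher on random tables", {
  set.seed(77)
  for (k in 1:20) {
    cand <- random_candidates(sample(5:40, 1))
    got <- build_matches(cand)
    ref <- reference_greedy(as.data.frame(cand))
    expect_equal(got$exposed_id, ref$exposed_id)
    expect_equal(got$control_id, ref$control_id)
    expect_equal(got$match_score, ref$score)
    # a control never serves twice; caps respected
    expect_false(any(duplicated(got$control_id)))
    expect_true(all(table(got$exposed_id) <= 4))
  }
})

test_that("greedy priority and caps behave on constructed toys", {
  # one control eligible for two exposed: goes to the lower score
  cand <- data.table::data.table(
    exposed_id = c("e1", "e2"), control_id = "c1",
    locality = c(5, 10), near_road = c(5, 10), year_penalty = 0,
    score = c(10, 20))
  got <- build_matches(cand)
  expect_equal(got$exposed_id, "e1")

  # one exposed, two eligible controls: both matched
  cand2 <- data.table::data.table(
    exposed_id = "e1", control_id = c("c1", "c2"),
    locality = c(5, 6), near_road = 0, year_penalty = 0, score = c(5, 6))
  expect_equal(nrow(build_matches(cand2)), 2)

  # cap at max_controls
  cand3 <- data.table::data.table(
    exposed_id = "e1", control_id = sprintf("c%d", 1:6),
    locality = 1:6, near_road = 0, year_penalty = 0, score = 1:6)
  expect_equal(build_matches(cand3, max_controls = 4)$control_id,
               c("c1", "c2", "c3", "c4"))

  # control reuse only when allowed
  expect_equal(nrow(build_matches(cand, max_controls = 4,
                                  allow_control_reuse = TRUE)), 2)
})

test_that("deterministic: identical inputs give identical matches", {
  set.seed(123)
  cand <- random_candidates(60, n_exposed = 8, n_control = 8)
  m1 <- build_matches(cand)
  m2 <- build_matches(data.table::copy(cand))
  expect_identical(m1, m2)
})

test_that("cross scoring agrees with the scalar score on a constructed layout", {
  segs <- segment_roads(straight_road(1000, years = 2010:2012), 10)
  residences <- data.frame(
    residence_id = c("e1", "c1", "c2"),
    x = c(500, 505, 700), y = c(120, -110, -300), stringsAsFactors = FALSE)
  exposure <- data.frame(
    residence_id = c("e1", "c1", "c2"),
    max_segment_id = c("roadA_s0050", NA, NA),
    nearest_dist = c(120, 110, 300),
    max_hours = c(100, 10, 20), stringsAsFactors = FALSE)
  groups <- data.frame(residence_id = c("e1", "c1", "c2"),
                       max_hours = c(100, 10, 20),
                       group = c("exposed", "control", "control"),
                       stringsAsFactors = FALSE)
  records <- data.frame(residence_id = c("e1", "c1", "c2"),
                        birth_year = c(2010, 2011, 2012), stringsAsFactors = FALSE)
  cand <- match_candidates(groups, exposure, residences, records, segs,
                           threshold = 1e6)
  seg <- segs[segs$segment_id == "roadA_s0050", ]
  for (i in seq_len(nrow(cand))) {
    ci <- cand[i, ]
    r_c <- residences[residences$residence_id == ci$control_id, ]
    sc <- match_score(
      sqrt((500 - seg$xm)^2 + (120 - seg$ym)^2),
      sqrt((r_c$x - seg$xm)^2 + (r_c$y - seg$ym)^2),
      120, exposure$nearest_dist[exposure$residence_id == ci$control_id],
      2010, records$birth_year[records$residence_id == ci$control_id])
    expect_equal(ci$locality, sc$locality)
    expect_equal(ci$near_road, sc$near_road)
    expect_equal(ci$score, sc$score)
  }
  # the year-window rule rejects candidates outright
  records$birth_year[3] <- 2015
  cand2 <- match_candidates(groups, exposure, residences, records, segs,
                            threshold = 1e6)
  expect_false("c2" %in% cand2$control_id)
})

test_that("matched pairs sit on opposite road sides under a prevailing wind", {
  cfg <- sim_config(seed = 8, n_residences = 600L, n_roads = 1L,
                    road_orientation_range = c(0, 0),   # road axis east-west
                    wind_kappa = 4, study_years = c(2012L, 2013L))
  sim <- simulate_cohort(cfg)
  res <- run_matched_analysis(sim, "tbw", "base")
  share <- opposite_side_share(res$matches, sim$exposure, sim$residences,
                               sim$segments)
  expect_gte(share, 0.95)
})

test_that("balance table shows the designed exposure contrast and covariate balance", {
  sim <- small_sim()
  res <- run_matched_analysis(sim, "tbw", "base")
  bal <- balance_table(res$matches, sim$records, sim$exposure)
  pdm <- bal[bal$variable == "pct_downwind_max", ]
  expect_gt(pdm$exposed, pdm$control)
  age <- bal[bal$variable == "maternal_age", ]
  # ~190 pairs; age sd 5.5 puts 3.5 sampling SDs at about 2 years
  expect_lt(abs(age$exposed - age$control), 2)
})
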