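# windmatch

Wind-direction instrumental-variable assessment of traffic-related air
pollution (TRAP) exposure, with downwind/upwind matched analysis of birth
outcomes.

## The problem

Residences near high-traffic roads experience more air pollution, but also
more noise, different neighbourhood composition, and different
socioeconomic context, so conventional road-proximity comparisons of birth
outcomes are heavily confounded. Wind direction offers an instrument:
neighbours on opposite sides of the same road share the non-pollution
exposures, yet the one living predominantly *downwind* receives far more
traffic pollution. Comparing matched downwind (exposed) and upwind
(control) neighbours isolates the wind-dispersed pollution component.

`windmatch` implements that design end to end for users who want to apply
it to their own cohorts or study its statistical behaviour:

1. **Exposure assessment.** High-traffic roads (AADT ≥ 25,000 vehicles/day)
   are cut into 10-m segments. For each pregnancy, hourly ERA5-style u/v
   wind vectors are converted to from-directions and accumulated into a
   360-bin radial distribution: in every hour the bins within ±15° of the
   from-direction (a 31° window at 1° resolution) are incremented. The
   hours downwind of segment *l* for residence *i*,
   `d_li`, are read off at the integer-degree bearing from the residence to
   the segment midpoint, for all segments within 500 m. Summaries per
   residence: mean hours downwind over the `n_i` segments, the *max road*
   (the segment upwind the most hours, ties to the nearest segment), and
   hours/percent of pregnancy downwind of it.
2. **Matching.** Residences in the top and bottom quartiles of max-road
   downwind hours become exposed and control groups. Candidate pairs are
   scored with
   `match score = |dist_maxee − dist_maxec| + |dist_neare − dist_nearc| + 10·|year_e − year_c|`
   (distance to the exposed member's max road, own nearest-road distances,
   birth-year penalty), kept only if both distance components are < 100 m
   and the birth years are within ±4, and assembled greedily from the
   lowest scores (≤ 4 controls per exposed residence, each control used
   once).
3. **Analysis.** Linear regression for term birth weight (TBW, grams) and
   logistic regression for low TBW (< 2,500 g), preterm (22 to < 37 weeks)
   and very preterm (22 to < 32 weeks) birth on the matched individuals,
   with base and fully adjusted covariate sets, cluster-robust standard
   errors by matched set, and distance-, covariate- and time-stratified
   variants plus a continuous percent-downwind sensitivity model and
   building/tree shielding adjustment.
4. **Synthetic cohorts.** A generator produces roads, hourly winds
   (seasonal + interannual von Mises regimes), residences, footprints and
   birth records with *configurable injected downwind effects*, so the
   whole chain is testable and its parameter recovery measurable without
   any restricted data.

## Worked example

```r
library(windmatch)

cfg <- sim_config(seed = 11, n_residences = 4000)   # -30 g injected effect
sim <- simulate_cohort(cfg)
res <- run_matched_analysis(sim, outcome = "tbw", covariate_set = "base")
res$estimate[, c("outcome", "model", "point", "ci_low", "ci_high", "n_pairs")]
#>   outcome model     point    ci_low  ci_high n_pairs
#> 1     tbw  base -34.58011 -90.84636 21.68615     875

opposite_side_share(res$matches, sim$exposure, sim$residences, sim$segments)
#> [1] 1      # every matched pair is a pair of opposite-side neighbours

bal <- balance_table(res$matches, sim$records, sim$exposure)
bal[bal$variable %in% c("pct_downwind_max", "nearest_dist", "maternal_age"), ]
#>          variable   exposed    control
#>      maternal_age  28.18039  28.259429
#>  pct_downwind_max  25.40922   3.201354
#>      nearest_dist 305.37282 330.717906
```

The point estimate (−34.6 g, 95% CI −90.8 to 21.7) is the adjusted TBW
difference for living predominantly downwind; at 875 pairs the interval is
wide but covers the −30 g truth the generator injected. The balance table
shows the design working: an eight-fold contrast in percent of pregnancy
downwind of the max road (25.4% vs 3.2%) while maternal covariates and
road distance are nearly identical across groups.

Real data enter through `read_roads_geojson()` (planar-meter LineStrings
with `aadt_<year>` properties), `read_wind_csv()` (`timestamp,u,v`),
`read_footprints_geojson()`, and a residence/birth-record data frame; from
there the same `cohort_exposure()` → `assign_exposure_groups()` →
`match_candidates()` → `build_matches()` → `fit_downwind_model()` chain
applies.

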