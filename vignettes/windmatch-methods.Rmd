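---
title: "Wind as an instrument: methods and design choices in windmatch"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Wind as an instrument: methods and design choices in windmatch}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The design in brief

Traffic-related air pollution co-occurs with noise, road dust, and
socioeconomic gradients, so proximity-based exposure contrasts are
confounded. Wind direction relative to a road shifts pollution exposure
while being plausibly unrelated to who lives where: it satisfies the two
requirements of an instrumental variable. `windmatch` operationalises this
as a matched comparison — not a two-stage least-squares estimator — of
pregnant residents living predominantly downwind versus predominantly
upwind of the same high-traffic road.

## Exposure model

**Wind.** Hourly eastward (`u`) and northward (`v`) air-motion components
are converted to the direction the wind blows *from*, the reverse bearing
of `atan2(u, v)`. A residence is downwind of a road segment in a given
hour when the residence-to-segment bearing lies within ±15° (inclusive) of
the from-direction; with directions rounded to integer degrees this marks
exactly 31 one-degree radial bins per hour. We chose the inclusive
boundary so the marked window is exactly 31°; an exclusive rule would give
29 and contradict the stated window width. Calm hours (`u = v = 0`) and
missing hours mark no bin but still count in the pregnancy length `m`; a
configurable completeness threshold (default ≥ 95% of pregnancy hours with
usable wind) guards the computation.

**Pregnancy window.** Hours run from 00:00 on the conception day through
23:00 on the birth day inclusive, so a same-day window has 24 hours and a
280-day gestation 6,744.

**Radial join.** Each 10-m segment within 500 m (membership by midpoint
distance, inclusive) is assigned the integer-degree bin of the
residence-to-midpoint bearing. Hours downwind of the segment are the bin's
count. A midpoint can only straddle more than one degree closer than about
50 m; we accept that quantisation, and the test suite proves the binned
result equals a per-hour angular test exactly whenever from-directions are
integer degrees. Per-residence summaries: the mean over all `n_i` segments
(zeros included), the max-upwind segment — ties broken by the smaller
residence-midpoint distance, then lexicographic id for determinism — and
hours and percent of pregnancy downwind of it.

**Distances.** Two distance notions coexist deliberately. Segment
membership and the matching locality distance use the segment *midpoint*,
consistent with the bearing join. The regression covariate and the
near-road matching distance use the true point-to-segment minimum, because
they quantify proximity rather than feed the radial join.

## Matching

Exposed and control groups are the top and bottom quartiles of max-road
downwind hours; quartiles are linear-interpolation (type-7) quantiles over
the full within-500-m cohort, with inclusive boundaries on both sides. For
term-birth-weight outcomes the 37–42-week restriction is applied *before*
grouping and matching. The match score adds the locality score (absolute
difference of the two residences' distances to the exposed member's max
segment), the near-road score (absolute difference of own nearest-road
distances), and ten units per year of birth-year difference; candidates
more than four years apart are ineligible outright, and both distance
components must be strictly below 100 m (15/25/50 m in the stricter
sensitivity settings). Assembly is greedy in ascending score (ties: lower
locality, then stable input order), at most four controls per exposed
residence. We forbid control reuse by default — it keeps the variance
interpretation of matched sets clean — and expose `allow_control_reuse`
because the original description does not settle the question. A
tiny-instance enumeration oracle in the tests pins the greedy semantics.

## Regression models

Linear models report grams for term birth weight; logistic models report
odds ratios for low TBW, preterm and very preterm birth. The base
covariate set is infant sex, maternal age (linear), birth month and year
(categorical), distance to nearest road (linear) and county (fixed
effect), plus gestational week (categorical, one level per completed week)
for the TBW model; the full set adds race/ethnicity, foreign birth,
payment source, WIC participation, smoking, weight gain (linear), month
prenatal care began and neighbourhood income tertile. Reference levels are
the most frequent category. Standard errors are cluster-robust by matched
set (sandwich `vcovCL`); `plain_se = TRUE` reproduces an uncorrected fit,
since the original analysis does not state a pair-level variance
correction. Non-convergence — zero or saturated events, separation
(|log-odds| > 15 or a huge standard error), iteration failure — is
reported as `converged = FALSE`, never raised, mirroring "did not
converge" table entries. Distance strata assign a pair by the exposed
member's own nearest-road distance; covariate strata likewise use the
exposed member's value and drop the stratifier from the covariate list;
rolling windows tile the exposed birth years with stride one. Matched sets
with any member missing a modelled value are dropped whole and counted in
the estimate's `note`.

## Shielding

The region between a residence and a segment is the triangle on the
segment endpoints and the residence — the simplest region consistent with
a 10-m segment, degrading to zero area (shielding 0, with a warning) when
collinear. Footprints are clipped to the triangle (Sutherland–Hodgman) and
their union area — computed exactly by a vertical sweep with breakpoints
at all vertices and edge crossings — is divided by the triangle area, so
stacked footprints never double-count. Shielding enters analysis only as a
pair of linear covariates; constant columns are dropped, reproducing the
unadjusted fit, and a shielding column collinear with exposure is removed
with a note rather than poisoning the fit.

## The synthetic cohort generator

The generator emulates the four study inputs in planar meters under one
master seed (each layer reseeds at a fixed offset, so layers are
reproducible standalone too).

* **Roads.** Six roads of 2 km by default, each gently meandering, placed
  in separate corridor cells at random orientations. Orientation
  diversity matters: with every road perpendicular to the prevailing
  wind, percent-downwind collapses onto a two-point distribution and the
  exposure quartiles degenerate. AADT is drawn above 25,000 with
  probability 0.8 (at least one high-traffic road is guaranteed),
  constant across years.
* **Wind.** Hourly from-directions are von Mises with concentration
  κ = 1.5 around a prevailing direction of 160° (a persistent
  south-south-easterly regime), with a ±45° annual sinusoidal swing and
  year-level variability of both the mean direction (sd 15°) and the
  concentration (log-sd 0.35). The seasonal and interannual terms give
  pregnancies starting in different months and years genuinely different
  wind climates; without them every same-side residence attains an
  identical percent-downwind ceiling and the top quartile of absolute
  hours is decided by pregnancy duration alone. Speeds are gamma
  (shape 2, scale 2.2 m/s). One site serves the whole area, matching the
  coarse-grid character of reanalysis wind.
* **Residences and footprints.** Residences sit on both sides of
  high-traffic roads at 10–500 m perpendicular offset, both uniform;
  rectangular building footprints and octagonal tree canopies are
  scattered over the same band at 40 per km² each.
* **Births.** Birth dates are uniform over 2007–2016; gestational weeks
  follow a weekly distribution with about 8% preterm and 1.5% very
  preterm mass; conception is birth minus seven times the gestational
  weeks, as a clinical conception estimate is not available to a
  generator. Covariates are drawn with no dependence on road side, making
  the instrument valid by construction; term birth weight is normal
  (3300 g at 39 weeks, sd 450, 130 g per week) with documented covariate
  effects.
* **Effect injection.** The term-birth-weight effect (default −30 g)
  attaches to the indicator "top quartile of max-road downwind hours
  within the term cohort" — a deterministic function of the true computed
  exposure that coincides with the contrast the matched analysis
  estimates, so recovery is attenuation-free; a `linear` mode injects
  grams per 10% downwind for the continuous sensitivity model, and
  `effect_decay_length` multiplies either by `exp(-d/decay)`. Preterm and
  very-preterm log-odds increments shift the gestational-age *category*
  through a logistic adjustment of the baseline category probabilities,
  re-drawing the week from the same retained uniform — a zero effect
  reproduces the baseline draw bit for bit, and the binary outcomes stay
  consistent with the recorded weeks (low TBW is weight-derived and
  receives no separate injection). The grams actually added are stored in
  `true_tbw_effect`, so simulation truth is always recoverable.
* **Confounding switch.** With `confounding = TRUE`, smoking probability
  rises towards the road on both sides (never differing by wind side).
  A naive unadjusted near/far regression is then biased, while the
  matched downwind estimate stays near truth — the design's central
  claim, demonstrated in the test suite.

## What the simulations show — and what they cannot

Validation sizes were chosen to make each question answerable on one CPU:
parameter recovery uses 50 replicates of ~24,000 residences (~5,000
matched pairs each) over a three-year cohort; null calibration 50
replicates at 2,000; the distance-decay and confounding demonstrations 20
replicates each at 8,000 and 6,000, with the decay amplitude set to
−120 g at the road so the gradient is resolvable at that scale.

Passing these tests shows the chain recovers what it injects under its
own assumptions: stationary-by-year winds from one site, straight-ish
isolated roads, outcomes exactly linear/logistic in the stated terms,
random covariates. They do not show robustness to dispersion physics
(street canyons, turbulence — no plume model is attempted), residential
mobility during pregnancy, geocoding error, or correlated real-world
covariate structure.

Two structural behaviours of the method itself surface clearly in the
synthetic world and deserve attention when interpreting real analyses.
First, few residences very near a road qualify as upwind controls — the
closer the house, the wider the range of wind directions that count as
downwind — so 0–50 m strata are chronically sparse and often do not
converge. Second, quartiles of *absolute* downwind hours mechanically
disfavour shorter pregnancies (fewer hours at equal percent downwind);
when exposure heterogeneity across residences is modest this depresses
preterm odds ratios below one under a true null. The percent-downwind
continuous model does not share this artefact. Both behaviours are
properties of the hour-quartile design, not implementation errors, and
both are documented by tests.

## Numerical choices

Bearings and bins are integer degrees in [0, 360); bin 0 is north.
Quantiles are type 7 throughout. The radial accumulation uses per-bin
prefix sums over the hourly series and a circulant window-sum, so cohorts
are linear in residences plus hours. Nearest-segment distances prune by
midpoint distance (exact within half a segment length, with a full scan
fallback near the pruning boundary). Greedy assembly runs in compiled
code after an R-level sort. Polygon union area uses exact slab
integration rather than Monte Carlo so shielding tests can assert exact
fractions. GeoJSON I/O assumes coordinates already projected to planar
meters; wind I/O uses the CSV layout (`timestamp,u,v`) — NetCDF input is
out of scope for this build. All randomness flows from one integer seed.
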