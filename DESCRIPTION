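Package: windmatch
Title: Wind-Direction Instrumental-Variable Exposure Assessment and
    Downwind/Upwind Matched Analysis of Birth Outcomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for assessing traffic-related air pollution exposure with
    wind direction as an instrumental variable. Converts hourly u/v wind
    vectors into per-pregnancy radial distributions of hours downwind of
    10-m high-traffic road segments, matches exposed (predominantly
    downwind) maternal residences with upwind controls on the same road by
    a distance-and-year match score, computes building and tree shielding
    fractions, and fits linear and logistic regression models for term
    birth weight and preterm-birth outcomes on the matched individuals with
    cluster-robust standard errors. Includes a synthetic geospatial cohort
    generator (roads, hourly winds, footprints, birth records with
    configurable injected downwind effects) so the full pipeline can be
    exercised and validated by simulation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    data.table,
    jsonlite,
    sandwich,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
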