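Package: heatpmcc
Title: Case-Crossover Analysis of Joint Heat Index and PM2.5 Effects on Hospitalization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for time-stratified case-crossover studies of joint heat
    and fine particulate matter (PM2.5) exposure, motivated by analyses of
    all-cause hospitalization in cohorts with Alzheimer's disease and related
    dementias. Implements the National Weather Service heat index, grid-to-ZIP
    exposure aggregation, climate-subtype heat-index percentiles, 3-day moving
    averages, cohort eligibility filters with time-stratified referent
    selection, B-spline and tensor-product crossbasis exposure terms,
    conditional logistic regression by direct maximization of the stratified
    likelihood, odds-ratio contrasts with delta-method intervals,
    exposure-response curves and interaction surfaces, a two-stage analysis of
    the PM2.5-heat dependence with Monte Carlo uncertainty propagation, and a
    synthetic-data generator so every stage can be validated against known
    truth without access to claims data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    splines,
    MASS,
    yaml
Suggests:
    testthat (>= 3.0.0),
    survival,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
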