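Package: cpree
Title: Resting Energy Expenditure Assessment in Children with Spastic
    Quadriplegic Cerebral Palsy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for assessing resting energy expenditure (REE) in
    children and adolescents with spastic quadriplegic cerebral palsy.
    Implements the common pediatric REE prediction equations (WHO,
    Schofield, Harris-Benedict, Oxford, Mifflin) together with two
    population-specific formulas for cerebral palsy, indirect-calorimetry
    processing (steady-state detection on breath-by-breath gas exchange
    and the abbreviated Weir equation), method comparison against
    calorimetry via Bland-Altman analysis with proportional-bias testing,
    Carstensen sloped limits of agreement and bidirectional conversion
    equations, Lin's concordance correlation coefficient, development and
    bootstrap optimism-corrected validation of a weight plus triceps-
    skinfold linear model (with restricted cubic spline nonlinearity
    testing and limited backward selection), and a points-based predictive
    nomogram. A synthetic cohort generator emulating the target clinical
    population makes the full pipeline reproducible without patient data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
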