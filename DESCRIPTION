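Package: hiplife
Title: Fatigue-Life Prediction of Hip Prosthesis Femoral Components
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Predicts the durability of a hip prosthesis femoral stem,
    expressed as months to aseptic loosening, from four patient-specific
    quantities: body mass, femoral offset, daily physical-activity time,
    and a lifestyle load coefficient. The core is a three-parameter
    power-law (Basquin-type) fatigue model whose contact stress combines
    eccentric compression, bending and torsion; the three coefficients are
    calibrated exactly from any three patients by a one-dimensional
    log-collinearity root-find. Includes the published 18-patient
    reference cohort for the non-cemented RCM stem, activity-score to
    load-coefficient mappings, a validation suite (error metrics,
    Mann-Whitney U with an exact permutation null, Pearson correlations,
    an ordinary-least-squares regression baseline), triplet
    cross-validation with t-based parameter confidence intervals, a
    synthetic-cohort generator, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
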