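Package: bagtraj
Title: Brain-Age-Gap Trajectories over Estimated Years to Symptom Onset
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for brain-age-gap (BAG) studies of autosomal
    dominant Alzheimer disease cohorts. Calibrates raw brain-predicted ages
    against chronological age in non-carrier controls to correct regression
    dilution, harmonizes predictions across acquisition sites with a
    single-variable empirical-Bayes (ComBat-style) batch model, models BAG and
    other MRI measures as nonlinear functions of estimated years to symptom
    onset (EYO) with penalized-spline generalized additive mixed models and
    family random effects, derives simultaneous 83.4% confidence bands and
    earliest-divergence EYO estimates with bootstrap comparisons across
    measures, and fits mixed-effects biomarker association and bootstrap
    mediation models. Includes a synthetic-cohort generator with known ground
    truth that emulates the structure of multi-site family-based ADAD studies
    for end-to-end testing and parameter-recovery validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    mgcv,
    lme4,
    lmerTest,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
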