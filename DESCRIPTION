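Package: capsthresh
Title: Responder-Threshold Analysis of Sustained Treatment Response in CAPS-5 Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for detecting a responder threshold in pre/post/follow-up
    clinical outcome data scored with the Clinician-Administered PTSD Scale
    (CAPS-5). Implements baseline-normalized outcome ratios, the responder-fraction
    curve over a grid of improvement thresholds, a permutation null obtained by
    shuffling follow-up ratios across participants, and the maximal-distance
    (elbow) threshold estimate with a selection-aware permutation p-value.
    Includes cluster-wise Spearman/Pearson association analyses with bootstrap
    inference, Mann-Whitney baseline-severity checks, and two synthetic-cohort
    generators: a parametric planted-threshold engine for calibration studies and
    a mechanistic bistable (double-well) stochastic simulator of treatment
    response.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
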