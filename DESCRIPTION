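Package: opajem
Title: Quantitative Job Exposure Matrices for Occupational Physical
    Activity During Pregnancy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Constructs quantitative, trimester-specific job exposure
    matrices (JEM) for occupational physical activity (standing, walking,
    forward bending) from repeated per-workday accelerometer summaries and
    multi-rater expert assessments over a hierarchical occupation coding
    system. Workdays are validated and duration-normalized to 8-hour
    time-weighted averages; categorical expert ratings are imputed across
    the code hierarchy, checked for inter-rater agreement (ICC), and
    calibrated to hours per workday; exposure levels are modelled by
    linear mixed-effects models (REML) with job and worker random
    intercepts and age, trimester and expert-rating fixed effects;
    measured jobs receive BLUP-adjusted entries and unmeasured jobs
    model-driven expert-based entries. A synthetic-cohort generator with
    recorded ground truth supports parameter-recovery testing of the
    whole pipeline at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    lme4,
    stats,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
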