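Package: enrollfit
Title: Relative Age Effects in Child Physical Fitness via Keyage-Referenced Delta z-Scores
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing how the timing of school enrollment relates to
    physical fitness in primary-school cohorts tested with a five-test battery
    (6-min run, star run, 20-m sprint, standing long jump, 1-kg ball push).
    Classifies children into keyage, older-than-keyage (OTK) and
    younger-than-keyage (YTK) enrollment groups from birthdate and a cutoff
    date, converts timed tests to pace scores, applies two-stage z-score
    standardization with cell-wise outlier removal, fits a keyage reference
    linear mixed model with crossed random effects for child, school and
    assessment year, predicts age-expected performance for non-keyage children,
    and models the resulting delta z-scores with sequential-difference test
    contrasts. Includes a synthetic cohort generator with retrievable ground
    truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    lme4,
    MASS,
    Matrix,
    dplyr,
    tibble,
    rlang,
    ggplot2,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml,
    withr
Config/testthat/edition: 3
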