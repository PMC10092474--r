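Package: idqiaq
Title: Scoring, Diagnostics and Psychometrics for the ICD-11 Depression
    and Anxiety Questionnaires (IDQ/IAQ)
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Implements the International Depression Questionnaire (IDQ)
    and International Anxiety Questionnaire (IAQ): severity sum scores,
    the ICD-11 diagnostic algorithms (core-symptom, symptom-count and
    functional-impairment rules), PHQ-9/GAD-7 comparator caseness, and
    prevalence estimation with Wilson score intervals.  Provides a
    normal-ogive item response theory engine for binary endorsement data
    (1- and 2-parameter models fitted by marginal maximum likelihood with
    an EM algorithm and Gauss-Hermite quadrature), tetrachoric
    correlations, likelihood-ratio model comparison, item information and
    characteristic curves, and limited-information fit indices.
    Reliability (McDonald's omega, Cronbach's alpha, item-total
    correlations), descriptive and group-comparison statistics (skewness
    with standard error, pooled t tests, one-way ANOVA from raw data or
    published summary statistics with Scheffe post hoc tests) round out
    the validation toolkit.  A synthetic-cohort generator reproduces the
    statistical structure of the instruments' UK community validation
    sample so the whole pipeline can be exercised without access to the
    original data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    e1071,
    mvtnorm,
    pracma,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
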