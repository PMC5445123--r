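Package: zhscreen
Title: Person-Fit Outlier Screening for Ordinal Questionnaires via the
    Graded Response Model
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits the multidimensional graded response model to ordinal
    questionnaire data by marginal maximum likelihood (EM with fixed
    quadrature), assesses overall fit with the limited-information reduced
    M2 statistic, and computes lz/Zh person-fit statistics to flag
    respondents whose item-response patterns are atypical under the model
    even when their subscale totals look average. Includes subscale
    scoring, conventional boxplot outlier detection for comparison, a
    published calibration of the CushingQoL quality-of-life instrument,
    and a synthetic-cohort generator with labelled aberrant responders
    (random, extreme-alternating, midpoint) for validating the screening
    pipeline end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    MASS,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
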