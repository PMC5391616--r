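Package: strokesynth
Title: Synthesis-Analysis Updating and Censored-Data Evaluation of Stroke
    Risk Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Extends a Framingham-style ten-year stroke risk score with
    literature-derived risk factors via synthesis analysis, recalibrates
    predicted risks against the Kaplan-Meier observed incidence, and
    compares competing risk models on censored follow-up data using
    Harrell's and Uno's concordance statistics, a survival
    Hosmer-Lemeshow test, and class and classless net reclassification
    improvement with percentile-bootstrap confidence intervals.  Includes
    a proportional-hazards cohort simulator with a closed-form risk
    oracle so that the full scoring and evaluation pipeline can be
    validated against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    survival,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
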