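Package: markercal
Title: Cross-Platform Calibration and Concordance of Quantitative Tumor
    Marker Assays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Validates agreement between two continuous-score biomarker
    quantification platforms and transfers prognostic cutpoints across them.
    Implements the extended Bland-Altman (Carstensen) assay-comparison model
    with bidirectional linear conversion equations and limits of agreement,
    Lin's concordance correlation coefficient, Cohen's kappa for dichotomized
    classifications, replicate coefficient-of-variation summaries, data-driven
    survival cutpoint discovery by log-rank scanning with cross-validation
    support, Kaplan-Meier/log-rank/Cox recurrence-free survival analysis, and
    inverse-probability-of-censoring-weighted time-dependent ROC curves.
    Includes a synthetic tissue-microarray cohort generator emulating paired
    platform scores, censored recurrence outcomes, pathologist chromogen
    scores, and operator replicates, so the full pipeline is testable without
    patient data.
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
    purrr,
    readr,
    rlang,
    stats,
    survival,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    e1071,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
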