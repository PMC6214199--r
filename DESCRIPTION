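Package: survscreen
Title: Screening and Variable Selection for Ultra-High-Dimensional
    Survival Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Sure independence screening (aggressive SIS, iterative SIS and
    principled SIS) combined with penalized Cox regression (LASSO, adaptive
    LASSO) and random-survival-forest minimal-depth thresholding for building
    prognostic models of right-censored outcomes from hundreds of thousands
    of genotyped variants. Includes a Hardy-Weinberg SNP survival simulator
    with censoring-rate calibration, discrimination (Harrell's c-index),
    overall-performance (IPCW Brier-score R-squared) and calibration metrics
    with bootstrap optimism correction, SNP quality-control filters, and a
    replicated benchmark driver.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    parallel,
    survival,
    glmnet,
    ranger,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
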