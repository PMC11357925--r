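Package: mrmediate
Title: Two-Sample and Two-Step Mendelian Randomization with Mediation
    Decomposition
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for two-sample Mendelian randomization (MR) on GWAS
    summary statistics: instrument selection with greedy LD clumping and
    R-squared/F strength filtering, allele harmonization with palindromic
    variant handling, five causal estimators (inverse-variance weighted,
    MR-Egger, weighted median, simple and weighted mode), heterogeneity,
    pleiotropy, outlier (MR-PRESSO style) and leave-one-out diagnostics,
    and two-step mediation analysis decomposing a total causal effect into
    direct and mediator-carried components.  Includes a summary-level GWAS
    simulator with known causal structure for end-to-end validation and a
    screening pipeline for many exposures and candidate mediators.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
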