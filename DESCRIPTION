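Package: mtgblup
Title: Single- and Multi-Trait GBLUP Genomic Prediction with AI-REML and
    Cross-Validation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Genomic evaluation toolkit for family-based aquaculture breeding
    designs. Simulates full-sib family populations with polygenic multivariate
    traits, performs SNP and individual quality control, builds the VanRaden
    genomic relationship matrix, fits single-trait and bivariate GBLUP animal
    models by average-information REML, derives heritabilities and genetic
    correlations with delta-method standard errors, and evaluates genomic
    prediction accuracy and bias under CV1/CV2 cross-validation masking
    schemes.
License: MIT
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
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
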