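Package: devtoxglr
Title: Germ-Layer Reporter Developmental Toxicity Screening Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for a germ-layer reporter developmental
    toxicity screen based on directed definitive-endoderm differentiation of
    pluripotent stem cells in 384-well plates. Provides a seedable
    synthetic-data generator emulating per-cell biomarker intensity tables
    and qPCR Ct panels, MAD-based biomarker-positive cell gating,
    ToxCast-pipeline-style concentration-response normalization, Hill and
    gain-loss curve fitting with AIC model selection, hit calling with ACC
    and AC50 potency estimation, robust plate quality-control metrics
    (signal-to-background, robust CV, robust Z'-factor), a gene-expression
    scorecard with delta-delta-Ct fold changes and Stouffer-type gene-set
    Z scores, and confusion-matrix benchmarking against packaged chemical
    reference tables.
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
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
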