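Package: lipidblocks
Title: Multi-Block PLS Regression Analysis of Plasma Lipidomic Intervention Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for two-arm dietary-intervention plasma lipidomics
    measured by LC-MS: shorthand lipid nomenclature parsing, class-specific
    internal-standard normalization, organization of lipid species into
    per-class blocks with class-share normalization and a "sums of lipids"
    block, baseline-adjusted log2 transformation, multi-block partial least
    squares regression (MBPLSR) with super and block scores, cross-validation
    with RMSECV component selection, jack-knife significance testing of
    regression coefficients, Hotelling T2 score outlier flagging, and
    univariate fold-change screening with Student's t tests and Storey
    q-values. Includes a synthetic study generator that emulates within-class
    fatty-acyl remodeling at constant class totals, with ground-truth effect
    labels for validating every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    mixOmics
Config/testthat/edition: 3
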