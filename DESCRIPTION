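Package: maskmix
Title: Mixture-Model Analysis of Masking and Temporal Crowding in Continuous Report
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis pipeline for continuous-report (orientation reproduction)
    experiments on visual masking and temporal crowding. Computes signed
    circular errors relative to target and distractors, applies trial- and
    participant-level exclusion rules, fits von Mises mixture models
    (standard, swap, two-misreport, and bias variants) by maximum a
    posteriori estimation, compares models with small-sample-corrected AIC
    (AICc), runs repeated-measures and mixed-design ANOVAs with partial eta
    squared and noncentral-F power analysis, and fits segmented (piecewise
    linear) regressions of model parameters against stimulus-onset
    asynchrony. Includes a synthetic-experiment generator that emulates the
    designs so every stage of the pipeline can be validated by parameter
    recovery without access to raw experimental data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
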