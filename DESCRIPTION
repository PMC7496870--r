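Package: aglmeta
Title: Multilevel Meta-Analysis of Artificial Grammar Learning Experiments
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Harmonizes heterogeneous artificial-grammar-learning (AGL) study
    outcomes into small-sample-corrected standardized mean differences
    (Hedges' g) with sampling variances, fits a three-level random-effects
    meta-regression (effects nested within articles) by restricted maximum
    likelihood with t-method inference, runs omnibus moderator F-tests,
    subgroup estimation, Cochran's Q heterogeneity tests and Peters'
    regression test for funnel-plot asymmetry, and provides a synthetic
    coding-sheet generator with the same nested variance structure so the
    whole pipeline is testable without external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    metafor,
    ggplot2,
    jsonlite,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
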