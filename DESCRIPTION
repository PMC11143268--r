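Package: phenostate
Title: Alternative Stable States in Evergreen and Deciduous Forests
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to test for alternative stable states in forest leaf
    phenology (evergreen versus deciduous) from two-census forest
    inventories. Implements plot-level relative evergreen abundance and
    inclusion filters, a zero-adjusted Poisson environmental null model
    with Monte-Carlo envelopes and a Spearman coupling test, generalized
    additive models of tree growth, survival and recruitment with a
    con-phenological feedback predictor, an individual-based forest
    succession simulator with stand-replacing disturbance and hysteresis
    experiments along a temperature gradient, Hartigan's dip statistic
    and a skewness-signed bimodality index with spatial and environmental
    clustering, and bootstrap permutation importance of climatic and
    edaphic drivers. A synthetic-data generator with exactly calibrated
    demographic feedbacks makes the whole pipeline testable end to end.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    splines,
    mgcv,
    e1071,
    ranger,
    jsonlite,
    yaml,
    Rcpp
LinkingTo:
    Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
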