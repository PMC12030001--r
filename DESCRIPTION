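Package: fluorosel
Title: Chlorophyll Fluorescence Based Yield Prediction and Indirect
    Selection for Multi-Environment Maize Trials
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for in-season prediction of maize grain yield and grain
    moisture from dark-adapted chlorophyll-a fluorescence induction (OJIP)
    transients. Derives the JIP-test biophysical parameter set (including
    the performance index on absorption basis) from Handy-PEA style
    transient exports, fits single-response partial least squares models
    with ten-fold cross-validation and RMSEP-based latent-variable
    selection, estimates variance components, progeny-mean heritability and
    genetic correlations on balanced multi-year trials by expected mean
    squares, and quantifies the efficiency of indirect selection on the
    predicted traits. A seeded synthetic-trial generator reproduces the
    statistical structure of a 16-hybrid, three-year, four-replicate trial
    so the full workflow is testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    jsonlite,
    yaml,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    lme4,
    mixOmics,
    optparse,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
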