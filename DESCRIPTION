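Package: omicforge
Title: Multi-Omics Compendium Normalization and Multi-Scale Predictive
    Modelling for Bacterial Molecular State and Growth
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Builds absolute-scale, quality-controlled multi-omics
    compendia (transcriptome, proteome, metabolome, fluxome, growth
    phenotypes) from heterogeneous relative-scale profiles, via a
    semi-supervised pipeline of mixture-model noise removal,
    platform-bias correction, loess absolute quantification and
    k-nearest-neighbour imputation.  On top of the compendium it trains
    a layered predictive model: a sigmoid recurrent network maps
    genetic and environmental condition features to genome-wide
    transcript levels; network-conditioned LASSO ensembles predict
    protein levels; l1-regularized regressions predict metabolite
    levels; expression-constrained flux balance analysis predicts
    fluxes; and a performance-weighted integrator predicts growth
    rate.  Includes a synthetic ground-truth generator, growth-curve
    feature extraction, growth-phase inference,
    leave-one-condition-out evaluation against standard baselines,
    expression-effect ontology reconstruction and coverage-driven
    knockout ranking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    boot,
    glmnet,
    mclust,
    e1071,
    jsonlite,
    limma,
    ape
Suggests:
    testthat (>= 3.0.0),
    pracma,
    withr,
    optparse
Config/testthat/edition: 3
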