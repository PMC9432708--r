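Package: cpgSieve
Title: Feature Selection Toolkit for Low-CpG Epigenetic Clocks
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for constructing epigenetic age-prediction clocks from
    small numbers of CpG sites. Implements percentage-based recursive
    feature elimination (%-RFE), shadow-feature (Boruta-style) all-relevant
    selection, genetic-algorithm subset search, neural-network perturbation
    ranking, fast univariate and model-threshold selectors, and selector
    chaining. A cross-validated workflow aggregates per-fold selections,
    intersects and frequency-ranks them, and evaluates candidate CpG panels
    with elastic-net clock models, including external validation and
    cross-dataset feature transfer. A synthetic methylation data generator
    with planted age-associated CpGs supports end-to-end testing without
    array downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    SummarizedExperiment,
    glmnet,
    ranger,
    nnet,
    data.table,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr,
    rmarkdown
biocViews: Epigenetics, DNAMethylation, FeatureExtraction, Regression,
    MethylationArray, Software
Config/testthat/edition: 3
RoxygenNote: 7.3.3
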