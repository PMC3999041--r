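Package: nutrinet
Title: Microbiome Abundance Profiles and Co-Occurrence Networks Along a
    Child-Nutrition Gradient
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for analysing feature-by-sample microbiome abundance
    tables along a continuous nutritional gradient: WHO-style LMS growth
    Z-scores and a cumulative nutritional index with AH/BL/SM
    classification, read-count normalisation and rank-normalisation of
    abundance profiles, ReBoot permutation-bootstrap significance testing
    for correlations on compositional data, parametric and non-parametric
    group comparisons with Benjamini-Hochberg FDR control and
    Tukey-Kramer post-hoc tests, abundance-pattern clustering,
    co-occurrence network construction with NetworkAnalyzer-style graph
    properties, and a sliding-window analysis of network-topology trends.
    Includes a synthetic cohort generator with planted gradient taxa and
    co-occurrence hubs for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    igraph,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
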