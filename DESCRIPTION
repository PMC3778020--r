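Package: crossmed
Title: Multi-Environment QTL Mapping and Causal Mediation in Segregant Crosses
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for mapping growth and expression quantitative trait loci
    (QTLs) across multiple environments in a biparental yeast segregant cross,
    decomposing genetic effects on expression into environment-persistent and
    environment-dependent components, building a multi-environment growth
    genetic model by stepwise regression, and scoring candidate causal
    intermediate genes by Bayesian-network model comparison (BIC). Includes a
    kinship-corrected linear mixed model for association scans, Storey-
    Tibshirani false discovery rate estimation, selection-coefficient
    estimation from pooled deletion-collection assays with a moderated t-test,
    benchmarking of candidate rankings against deletion fitness data, and a
    seeded synthetic-cross generator that emulates the checkered experimental
    design used for expression profiling.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    limma,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
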