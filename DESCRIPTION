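Package: tfsarray
Title: Dye-Swap Two-Color Microarray Analysis of Developmental and
    Sex-Biased Liver Gene Expression
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: End-to-end analysis of dye-swapped two-color expression
    microarray comparisons of male and female mouse liver across postnatal
    development. Provides intensity-dependent (LOWESS) normalization,
    an error-weighted replicate-combination model with two-component
    (additive plus multiplicative) technology error, total-flagging-sum
    (TFS) encoding of per-gene regulation patterns across seven
    comparisons, classification of genes by sex specificity, onset age and
    developmental change, short-series model-profile clustering with a
    permutation significance test, gene-set overlap fold-enrichment
    statistics with an exact two-tail Fisher test computed in log space,
    and a synthetic-data generator with known per-gene truth for
    validating the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    yaml,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    ape,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
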