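Package: lncprop
Title: Pathway Annotation for lncRNA Sets by Network Propagation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Identifies biological pathways influenced by the combinatorial
    effect of a set of long non-coding RNAs (lncRNAs). Seed lncRNAs are
    propagated over a mixed coding/non-coding gene correlation network
    (consensus co-expression edges merged with protein-protein interactions)
    by random walk with restart; protein-coding genes are ranked by the
    square root of their steady-state visiting probability, and pathways are
    scored against the ranked list with a propagation-score-weighted
    Kolmogorov-Smirnov running-sum statistic. Significance is assessed by a
    seed-permutation null with Benjamini-Hochberg correction. Includes the
    co-expression pipeline used to build such networks from multi-dataset
    FPKM matrices (Fisher z, per-gene standardization, Bonferroni and rank
    filters, cross-dataset consensus), a synthetic-data generator with
    planted ground truth for validation, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    Matrix,
    jsonlite,
    optparse,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
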