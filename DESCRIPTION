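Package: MycoLoss
Title: Comparative Gene-Content Analysis of Mycoheterotrophic Plant Transcriptomes
Version: 0.9.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for comparing the gene content of non-photosynthetic
    (mycoheterotrophic) plants with photosynthetic relatives from assembled
    transcriptomes. Implements post-assembly filtering (major-isoform
    selection, coverage filter, six-frame CDS selection, best-hit taxonomy
    contamination removal, gene-level FPKM), reciprocal-best-hit 1-1
    orthology, group-wise GO-term enrichment with annotation propagation on
    the ontology DAG, Bonferroni group aggregation and Benjamini-Yekutieli
    FDR control, gene-loss parallelism statistics with a hypergeometric
    null, reconciliation of organellar-targeting predictions across two
    predictor styles and sequence variants, and likelihood-ratio-test
    classification of selection shifts. A seeded synthetic-data generator
    emulates every input so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
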