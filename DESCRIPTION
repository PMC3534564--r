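Package: mirmerge
Title: Consensus microRNA Target Prediction and Multi-Level Dataset Merging
Version: 1.0.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: A local, file-based toolkit for integrating microRNA and mRNA
    experiments against frozen snapshots of target-prediction and annotation
    databases. Provides consensus miRNA target prediction across multiple
    prediction sources, miRNA mature-sequence metadata and seed-region homology
    filtering for cross-species miRNA mapping, identifier cross-referencing and
    ortholog mapping with bidirectional percent identity, an ordered multi-level
    table merge engine with per-relation match accounting, batch GO/KEGG
    annotation (directly or via an ortholog bridge), hypergeometric gene-set
    enrichment against a declared background, and agglomerative centroid-linkage
    hierarchical clustering. A deterministic synthetic snapshot generator with a
    planted-fact ledger makes every step testable end-to-end without network
    access.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
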