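Package: superpath
Title: Superpathway Cross-Talk Analysis and Multi-Evidence Biomarker
    Screening for Two-Group RNA-Seq Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for prioritizing candidate biomarkers
    from a two-group bulk RNA-seq comparison, as applied to malignant versus
    nonmalignant canine prostate samples. Counts are normalized by
    median-of-ratios size factors and tested gene-wise with a
    negative-binomial Wald test; differentially expressed genes are mapped
    through an ortholog table and tested for pathway over-representation by
    the hypergeometric distribution; enriched pathways are clustered into
    superpathways by complete-linkage clustering of one minus the overlap
    coefficient; genes are then screened into three biomarker tiers
    (strongly deregulated superpathway genes, database-associated genes,
    and their intersection) and the database tier is analyzed as a
    protein-protein interaction network with mean-degree hub detection.
    A seeded synthetic-data generator with planted differential expression,
    planted pathway blocks and planted network hubs makes every stage
    testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    ape,
    DESeq2,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
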