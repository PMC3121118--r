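Package: bidipromoter
Title: Classification and Regulatory Analysis of Bidirectional Promoters
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Genome-wide analysis of head-to-head (divergent) gene pairs and
    their shared promoters. Collapses a refGene-style transcript table into
    strand-specific gene clusters, classifies bidirectional gene pairs
    (TSS-to-TSS distance under 1 kb) and uni-directional genes, extracts
    bidirectional (intergenic) and uni-directional (1 kb upstream) promoter
    sequences, detects CpG islands under the Gardiner-Garden and a stricter
    GC-content criterion, performs GO term enrichment with Benjamini-Yekutieli
    correction and within-pair shared-term analysis, scans promoters with
    JASPAR- and TRANSFAC-format position weight matrices on both strands, and
    classifies each motif as over-represented, shared or under-represented in
    bidirectional versus uni-directional promoters at a 2-fold threshold. A
    seeded synthetic-data generator plants gene layouts, CpG-island contrasts,
    motif instances and ontology annotations with a ground-truth manifest so
    the whole pipeline is testable without external genome downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    S4Vectors,
    igraph,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    rtracklayer,
    GenomicRanges,
    jsonlite
Config/testthat/edition: 3
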