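Package: mirwaves
Title: Developmental miRNA Expression Waves in Hemimetabolan Ontogeny
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for stage-resolved small-RNA sequencing of
    hemimetabolan insect development. Houses a miRNA catalog (biogenesis
    filtering of candidate hairpins, seed families, genomic clusters),
    quantifies reads into per-library counts with 3'-end nontemplated
    tail (adenylation/uridylation) profiling, performs stage-to-stage
    negative-binomial differential expression with median-of-ratios
    normalization, extracts Spearman-threshold coexpression modules with
    SVD metagenes, and compares family-level expression across species.
    A synthetic-data generator emulating an 11-stage, 2-replicate design
    with four coexpression waves and maternal loading supports
    parameter-recovery testing of the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    SummarizedExperiment,
    rtracklayer,
    igraph,
    ape,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mclust,
    DESeq2
Config/testthat/edition: 3
RoxygenNote: 7.3.3
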