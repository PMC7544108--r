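Package: otomap
Title: Multi-Omic Mapping of Hearing Difficulty GWAS Risk Loci to Cochlear Genes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An analysis pipeline that goes from GWAS summary statistics plus
    cochlear epigenomic and transcriptomic annotations to risk loci, heritability
    enrichment in cell-type open chromatin, gene-level and cell-type expression
    enrichment, and a tiered list of prioritized risk genes. Includes desk-scale
    (stratified) LD score regression with block-jackknife uncertainty, LD clumping
    and locus definition, a MAGMA-style gene test with a weighted-chi-square null,
    chain-based cross-species interval mapping with a minimum-matched-bases rule,
    GAT-style workspace permutation enrichment, a minimal single-cell RNA-seq
    pipeline with Wilcoxon markers and a Stouffer hair-cell meta-analysis,
    polygenic risk scoring, and synthetic-data generators that emulate the
    statistical structure of the real inputs so everything is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    Matrix,
    GenomicRanges,
    IRanges,
    S4Vectors,
    limma,
    igraph
Suggests:
    testthat (>= 3.0.0),
    rtracklayer,
    mclust,
    withr,
    jsonlite
Config/testthat/edition: 3
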