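Package: quadchrom
Title: Integrative Analysis of G-Quadruplex, Chromatin Accessibility and
    Expression Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for integrating G-quadruplex (G4) ChIP-seq peaks with
    chromatin accessibility (ATAC-seq) and gene expression (RNA-seq) data in
    two-condition designs such as disease-versus-control cell lines.
    Provides copy-number-aware normalization of peak count matrices before
    differential testing, a simplified negative-binomial differential stage,
    permutation and universe-resampling enrichment of genomic interval sets,
    strand inference for unstranded G4 peaks from strand-resolved G4-seq
    hits, hypergeometric quadrant tests for the concordance of differential
    calls across contrasts, promoter-based peak-to-gene linking, zFPKM
    expression activity calls, proximity-decay correlation analysis, and a
    type-III interaction model of expression change on accessibility and G4
    status. A synthetic study generator with planted ground truth makes the
    whole pipeline testable end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    rtracklayer,
    limma,
    car,
    yaml,
    withr,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    DESeq2,
    jsonlite
Config/testthat/edition: 3
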