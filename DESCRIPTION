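Package: umicount
Title: Digital Gene Expression Tag Counting with UMIs and
    Error-Correcting Sample Indexes
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A complete tag-counting pipeline for unique molecular
    identifier (UMI) based digital gene expression (DGE) profiling of
    multiplexed single-cell and low-input RNA-seq libraries. Designs and
    decodes 8-nt sample multiplex indexes with single-substitution error
    correction, demultiplexes paired read1/index-read FASTQ files while
    embedding the 10-nt UMI in the read name, resolves alignments to gene
    loci and unifies reads into UMI counts, estimates sequencing
    saturation by read subsampling, screens sample quality with
    correlation-based outlier detection and ERCC spike-in linearity, and
    provides the downstream statistics used with such data: TMM scaling
    factors, iterative DEG-exclusion (iDEGES-style) normalization, an
    exact negative-binomial two-group test with BH correction, and
    Hoeffding's D test of independence. A seeded read simulator with full
    ground truth makes every stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    Rsamtools,
    S4Vectors,
    data.table,
    Matrix,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    edgeR,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
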