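Package: screglink
Title: Regulatory Link Inference from Paired Single-Cell Chromatin
    Accessibility and Gene Expression
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Infers cis-regulatory-element to gene regulatory relationships
    from paired single-cell chromatin accessibility (peak x cell) and gene
    expression (gene x cell) count matrices using three complementary
    strategies: weighted Spearman correlation of promoter and distal peak
    accessibility, weighted Spearman correlation of distal peak accessibility
    and gene expression, and a per-cell active-region Wilcoxon test driven by
    regulon-based transcription-factor activity and motif scanning. The
    resulting binary link x cell matrix is decomposed by non-negative matrix
    factorization with cophenetic/Amari rank selection to separate cell
    identities. Additional components score per-cell transcription-factor
    chromatin accessibility deviations, validate links against chromatin
    interaction (BEDPE) data, and simulate paired multi-omic data with
    planted cell types, TF programs and regulatory links for benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Biostrings,
    pracma,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mclust,
    yaml,
    scran
Config/testthat/edition: 3
RoxygenNote: 7.3.3
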