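Package: archrep
Title: Gene Architecture and Repetitive-Element Analysis of Differential Gene Sets
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for relating gene architecture (exonic and intronic length,
    exonic content) and repetitive-element content to differential gene
    expression. Parses gene annotation (GTF) and RepeatMasker output, computes
    per-gene repeat density stratified by region (exon/intron) and orientation
    (sense/antisense), and tests gene sets for enrichment or depletion with a
    Monte Carlo resampling null (Z-scores, Kolmogorov-Smirnov tests, FDR).
    Includes cumulative-distribution length-bias curves, exhaustive pyknon
    (k-mer motif) search with repeat-family attribution and per-gene density
    normalisation, expression-matrix filtering with permutation-based
    differential abundance (on raw values or per-sample ranks) and
    hypergeometric overlap tests, and binarized-expression tissue signatures
    via one-vs-one linear support-vector machines with voting, an "Other"
    rejection class, and squared-weight variable importance. A synthetic-data
    module generates annotation, repeats, sequence, motifs and expression with
    known planted structure for end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Biostrings,
    rtracklayer,
    e1071,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
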