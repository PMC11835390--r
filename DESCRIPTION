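Package: utrstab
Title: RNA Stability Analysis for UTR Variant Reporter Time Courses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of massively parallel reporter assays that measure RNA
    decay of paired reference/mutant UTR fragments over a transcription-free
    time course. Estimates per-oligo decay constants and half-lives by
    weighted log-linear regression, tests allele effects on stability with a
    genotype-by-time interaction model, builds sequence and interval feature
    matrices (k-mer composition, AU-rich elements, Kozak contexts, PWM and
    miRNA seed scans, BED-track overlaps), performs collinearity-aware LASSO
    feature selection with VIF-bounded correlation clustering, discovers
    stabilizing/destabilizing 7-mer motifs by bootstrap penalized regression,
    profiles UA-dinucleotide composition along UTRs with permutation-based
    group enrichment, and fits SLAM-seq style half-lives from T-to-C
    conversion tables. A synthetic-data generator with known ground truth
    makes every stage testable end to end.
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
    glmnet,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
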