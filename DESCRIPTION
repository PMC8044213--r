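Package: methdyn
Title: Methylome Segmentation and DNMT3A-Dependent Differential Methylation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for whole-genome bisulfite sequencing (WGBS) methylome
    analysis centred on a two-state beta-binomial hidden Markov model for
    hypomethylated region (HMR) and methylation-canyon segmentation.
    Includes per-CpG differential methylation scoring with exact Beta
    posterior probabilities, differentially methylated region (DMR) calling
    with CpG-count and significance filters, three-condition construction of
    DNMT3A-dependent DMRs with pattern-vector classification by maximum
    Pearson correlation, joint 5mC/5hmC estimation from paired WGBS and
    TAB-Seq data with spike-in efficiency correction, genomic interval
    overlap statistics (Jaccard, reciprocal overlap, nearest-TSS, feature
    annotation, Fisher gene-set tests, binned meta-profiles), and a
    synthetic multi-condition methylome simulator with planted foundational
    and dynamic layers for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    BiocGenerics,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
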