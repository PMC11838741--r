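Package: cardiomosaic
Title: Somatic Mutation Burden, Signatures and Expression Consequences in
    Single Cardiomyocytes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis toolkit for single-cell whole-genome somatic mutation
    studies of post-mitotic heart muscle cells. Implements amplification
    quality scoring (MAPD, CoV, composite QC score), sensitivity-corrected
    genome-wide mutation burden estimation with a zero-depth refinement,
    linear mixed-effects models of burden against age and disease condition,
    SBS96 mutational spectrum construction, catalog signature refitting by
    non-negative least squares, de novo signature extraction by non-negative
    matrix factorization with cophenetic rank selection, trinucleotide
    context-preserving permutation tests of mutation enrichment against
    expression and chromatin accessibility, germline-normalized selection
    statistics, and a leave-one-out consensus differential-expression
    procedure. A synthetic cohort generator reproduces the statistical
    structure of such studies so every stage is testable without
    protected data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    rlang,
    withr,
    ggplot2,
    generics,
    lme4,
    lmerTest,
    pracma,
    jsonlite,
    yaml,
    Matrix,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    SummarizedExperiment,
    VariantAnnotation,
    stats,
    tools,
    utils,
    methods
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
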