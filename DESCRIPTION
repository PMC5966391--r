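Package: mirnaome
Title: miRNAome Profiling from Small RNA-Seq: IsomiRs, ADAR Editing,
    Expression Dynamics and miRNA Grouping
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for profiling the miRNAome of a differentiating cell
    system from small RNA-seq data. Parses miRBase-style references
    (hairpin/mature FASTA plus GFF3) and derives seeds, seed families and
    genomic clusters; classifies collapsed reads into exact/isomiR classes
    with templated/non-templated end additions, nucleotide substitutions
    and A-to-I (ADAR) editing candidates; filters and CPM-normalizes count
    matrices and runs a transparent negative-binomial Wald differential
    expression with volcano classification, sample distances and PCA;
    clusters standardized stage profiles by fuzzy c-means; aggregates
    expression by family and genomic cluster and selects a three-tier
    cell-type miRNAome; computes set-level statistics over externally
    produced target-prediction score tables; and generates synthetic
    references, reads, counts and score tables with planted ground truth
    for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    rtracklayer,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    e1071,
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
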