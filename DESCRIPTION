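Package: sexfst
Title: Inter-Sex FST and Sex-Linkage Analysis from Pooled Sequencing Read Counts
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Pipeline for detecting sex-linked genomic differentiation from
    pooled exome sequencing read counts. Implements per-SNP variance-component
    F_ST for pooled samples, Hardy-Weinberg expected heterozygosity per sex,
    the replicate-concordance and coverage filtering rules used for pool-seq
    SNP tables, gene-wise ratio-of-sums F_ST aggregation, sex-linkage
    classification and regional tests (one-sided t-tests for male
    heterozygosity excess, Fisher's exact chromosome enrichment, hypergeometric
    category over-representation, cross-population intersection, beta-fit
    diagnostics), and a synthetic pool-seq generator emulating proto-Y sex
    chromosome architecture for calibration and validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    ggplot2
Config/testthat/edition: 3
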