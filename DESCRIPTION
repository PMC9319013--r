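Package: breakscape
Title: Integrative Analysis of Recurrent DNA Double-Strand Breaks and
    Chromosome Structural Rearrangements
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline linking recurrent DNA double-strand
    breaks (DSBs) mapped by Break-seq to chromosome structural rearrangement
    breakpoints, copy-number changes, gene-feature enrichment, differential
    expression near breaks, and survival-relevant biomarker stratification.
    Provides a copy-number-normalized Poisson local-background DSB peak
    caller, replicate consensus and cross-line partition interval algebra,
    binary CNV segmentation from binned read counts, paired structural-variant
    breakpoint bookkeeping, permutation-calibrated DSB/breakpoint concordance,
    Fisher exact feature enrichment, one-way ANOVA differential expression,
    and Kaplan-Meier log-rank analysis with data-driven expression cut-off
    optimization. Ships a synthetic-data generator with known ground truth
    emulating a two-cell-line Break-seq/DNA-seq/RNA-seq/survival study so the
    whole pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    BiocGenerics,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    survival,
    optparse,
    knitr
Config/testthat/edition: 3
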