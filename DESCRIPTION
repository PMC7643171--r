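Package: ocrcell
Title: Cell-Type-Resolved Differential Chromatin Accessibility from ATAC-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A tidyverse-native pipeline for cell-type-resolved analysis of
    ATAC-seq open chromatin regions (OCRs): consensus peak construction and
    quality metrics (FRiP, PBC, TSS enrichment), promoter-anchored TMM
    normalization averaged over reference samples, PCA-based covariate
    screening with net-BIC forward selection, precision-weighted differential
    accessibility with cell/neuronal/region specificity set algebra,
    estimation of the proportion of non-null tests (pi1) across all group
    contrasts, genomic-context and gene-set overlap statistics,
    transcription-factor footprint regulatory burden with rank aggregation
    and coverage-aware binomial motif enrichment, and marker-OCR deconvolution
    of bulk case-control chromatin data. A synthetic-data module generates
    negative-binomial experiments with planted cell, region, sex and
    signal-allocation effects so that every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    GenomicRanges,
    IRanges,
    limma,
    purrr,
    quadprog,
    rlang,
    S4Vectors,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    withr,
    edgeR,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
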