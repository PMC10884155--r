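Package: chromlink
Title: Chromatin Openness Dichotomization and Enhancer-Gene Linkage for
    Two-Condition Epigenomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for integrating two-condition ATAC-seq, H3K27ac, Hi-C-style
    contact models, RNA-seq and TF ChIP-seq into regulatory calls: iterative
    score-per-million consensus peak merging, pseudo-input background peak
    calling with FDR-quantile thresholding to dichotomize chromatin into
    common and condition-specific open clusters, peak-to-gene linkage with
    fold-change filters and primed-promoter detection, Activity-by-Contact
    enhancer-gene scoring, TF-bound enhancer-promoter pair extraction, and
    knockdown-response gene classification. Ships a synthetic multi-omic
    data generator with ground truth so the whole pipeline is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    GenomicRanges,
    ggplot2,
    IRanges,
    jsonlite,
    purrr,
    readr,
    rlang,
    S4Vectors,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
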