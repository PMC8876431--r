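Package: methdmr
Title: Sliding-Window Differentially Methylated Region Calling and
    Methylome-Transcriptome Integration
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Hierarchical, context-aware calling of differentially methylated
    regions (DMRs) from per-cytosine bisulfite-sequencing reports: a 200-bp /
    50-bp sliding-bin scan with Fisher's exact test and Benjamini-Hochberg FDR
    control, per-cytosine DMC calling with context-specific absolute-difference
    thresholds (CG/CHG/CHH), retention of bins holding at least seven DMCs, and
    gap-bounded merging of neighbouring significant bins. Includes integration
    of DMRs with gene-expression tables (direction summaries, cross-timepoint
    overlap, fold-change correlation in positive and negative regimes, Wilcoxon
    comparison of expression shifts) and a seeded beta-binomial methylome
    simulator that plants ground-truth DMRs and coupled expression changes for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr (>= 1.1.0),
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
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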