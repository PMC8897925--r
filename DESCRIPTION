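Package: methylens
Title: Integrative Analysis of DNA Methylation, Chromatin Accessibility and
    Gene Expression in Differentiating Cells
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for linking whole-genome bisulfite sequencing methylation
    changes to chromatin accessibility and gene expression changes between two
    cell states, modelled on the epithelial-to-fiber differentiation of the eye
    lens. Provides a smoothed beta-binomial caller for differentially
    methylated regions (DMRs), strand-aware annotation of DMRs to genomic
    features with a random-placement null, per-gene methylation/expression
    correlation and quadrant association, DMR-by-ATAC-peak overlap
    classification, three-way integration of methylation, accessibility and
    expression, and position-weight-matrix motif scanning with exact
    score-distribution p-values and enrichment against shuffled backgrounds.
    A synthetic-data generator emulates the full data structure (replicate
    methylomes with planted DMRs, coupled expression and accessibility tables)
    so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    dplyr,
    GenomeInfoDb,
    S4Vectors,
    generics,
    ggplot2,
    IRanges,
    jsonlite,
    purrr,
    readr,
    rlang,
    rtracklayer,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
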