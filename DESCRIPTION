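Package: rfxtargets
Title: Integrative ChIP-Seq/RNA-Seq Identification of Direct RFX Transcription-Factor Targets
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested, reusable pipeline for calling direct transcription-factor
    target genes by integrating ChIP-seq binding evidence with knockout RNA-seq
    differential expression, modelled on the regulatory logic of RFX-family
    factors in mouse spermatogenesis. Provides windowed Poisson peak calling
    against an input control, promoter assignment of peaks around annotated
    transcription start sites, de novo X-box motif discovery by ZOOPS
    expectation-maximisation and log-odds PWM scanning, a negative-binomial
    exact test for two-group contrasts with fold-change tiers, developmental
    expression-profile consistency classification, ciliary-evidence scoring,
    and gene-set overlap statistics. A synthetic-data module generates every
    input with planted ground truth (regulon membership, binding sites, effect
    sizes) so the whole pipeline is testable end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    readr,
    rlang,
    stringr,
    ggplot2,
    generics,
    jsonlite,
    stats,
    tools,
    utils,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    S4Vectors,
    Biostrings,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    edgeR,
    DESeq2,
    optparse,
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
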