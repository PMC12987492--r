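Package: tsscall
Title: Comparative Transcription Start Site Calling from 5'-Enriched RNA-seq Coverage
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Detects and classifies bacterial transcription start sites (TSS)
    from paired 5'-enriched and non-enriched RNA-seq coverage profiles
    (dRNA-seq, Cappable-seq, tagRNA-seq). Implements two-stage inter-library
    normalization (percentile equalization followed by enrichment-factor
    equalization), step-height/step-factor candidate detection on per-base
    coverage, cross-replicate reconciliation with threshold reduction,
    enrichment filtering against the control library, cross-condition
    clustering, and gene-relative classification into primary, secondary,
    internal, antisense and orphan TSS. Also provides UpSet-style subset
    summaries, a Kolmogorov-Smirnov + Cauchy-combination differential TSS
    test, and a synthetic coverage generator with planted ground truth for
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    rtracklayer,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Biostrings,
    yaml,
    methods,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
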