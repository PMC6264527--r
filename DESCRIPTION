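Package: lncdiscover
Title: Discovery and Characterization of Embryonic Long Non-Coding RNAs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline that turns assembled embryonic transcript
    models plus expression, CAGE and conservation tracks into a
    high-confidence lncRNA catalogue. Implements the full filtering cascade
    (annotation overlap, intronic pre-mRNA removal, monoexonic strand-ratio
    and length rules, expression and repeat-content thresholds, isoform
    de-duplication, nuclear-enrichment ratio, read-through flagging, and a
    differential-expression partition into main and constitutive sets),
    CAGE-based transcription start site refinement, a two-of-three
    coding-potential voting classifier, mutually exclusive genomic-context
    classification, lncRNA to protein-coding-gene pairing with
    correlation-versus-random background tests, iterative k-means expression
    clustering, divergent bidirectional promoter transcription profiling,
    phastCons-element conservation scoring, strain-specific expression
    detection, and knockout-cross viability statistics. Ships a synthetic
    embryo-transcriptome generator with planted ground truth so every stage
    is testable end-to-end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    readr,
    purrr,
    rlang,
    stats,
    utils,
    jsonlite,
    yaml,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
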