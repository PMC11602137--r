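Package: dsbdart
Title: Strand-Resolved Nascent RNA Analysis Around Sequence-Specific
    DNA Double-Strand Breaks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A desk-scale, fully tested pipeline for analysing
    damage-associated RNA transcripts (DARTs) from stranded
    chromatin-associated RNA sequencing around sequence-specific
    double-strand breaks (AsiSI/DIvA-type systems). Builds CPM-normalised
    strand-resolved per-base coverage, extracts DSB-anchored flank
    matrices, annotates bins as sense or antisense relative to
    neighbouring gene orientation, stratifies break sites by cleavage
    efficiency, repair-pathway propensity and local transcription
    activity, and computes windowed log2 fold changes with rank-sum
    statistics and replicate PCA. Ships a synthetic-data generator with
    a machine-readable truth file so every stage can be validated
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    ggplot2,
    jsonlite,
    rtracklayer,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
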