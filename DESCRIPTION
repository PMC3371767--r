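Package: strandnorm
Title: Strand-Specific High-Resolution Normalization of ChIP-seq Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Removes experimentally measured background from ChIP-seq read
    data while preserving base-pair resolution and strand specificity.
    Strand-split read-start tracks are smoothed with a small moving-average
    window, resampled at regular centres, and the ChIP track is regressed on
    one or more control tracks (Input, IgG) by ordinary least squares without
    intercept, section by section along the genome. Positive regression
    residuals are exported as dummy reads in BED format so that any
    downstream tool that consumes aligned reads can consume the normalized
    signal. Includes a synthetic ChIP/control read simulator and a
    sense/antisense-distance fragment-size estimator.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    tools,
    optparse
Suggests:
    testthat (>= 3.0.0),
    rtracklayer,
    GenomicRanges,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
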