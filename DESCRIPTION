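Package: tiletx
Title: Tiling-Array Transcriptome Segmentation and Intergenic
    Transcription Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for genome tiling-array transcriptome data
    from staged embryonic tissue: background correction and quantile
    normalization of probe intensities, RMA-style median-polish
    summarization of exon and 500-bp window blocks, percentile-based
    expression thresholds calibrated on intergenic signal, gene and
    transcript expression calls, differential expression between stages
    against a genome-local coordinate-perturbation permutation null,
    detection and annotation-based classification of intronic and
    intergenic transcribed regions, and proximity/neighborhood statistics
    relating intergenic transcription to expressed genes.  Includes a
    synthetic-data generator that emulates the probe-level structure of a
    tiled two-replicate, three-stage design so that every stage of the
    pipeline is testable without array downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    limma
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
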