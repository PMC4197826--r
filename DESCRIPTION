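Package: ivtbias
Title: Assessing Technical Coverage Bias in RNA-Seq with In Vitro
    Transcribed Control Transcripts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying technical bias in RNA-seq coverage using
    pools of in vitro transcribed (IVT) control transcripts of known sequence.
    Reads genome-space coverage tracks (bedGraph) and transcript models
    (BED12), projects coverage into transcript space, and computes
    per-transcript uniformity statistics: FPKM, base-level coefficient of
    variation, within-transcript fold-change between coverage deciles, and
    the 3'/5' processivity ratio. Detects regions of high, unpredictable
    coverage (hunc regions) across an IVT:background dilution series with a
    sliding-window median-absolute-deviation caller, including replicate
    intersection and background-read filters. Associates coverage
    variability with sequence features (hexamer Shannon entropy, GC content,
    Smith-Waterman similarity to rRNA) through rank-based tests. A
    fragmentation-based coverage simulator with ground-truthed bias
    injection makes every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
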