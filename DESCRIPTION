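Package: chromfate
Title: Chromatin-Level Analysis of Cell Fate Transitions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analyses of chromatin-level control of cell fate transitions in
    the Arabidopsis stomatal lineage: per-cell transcriptional entropy from
    single-cell RNA-seq counts, ChIP-seq peak integration (overlap
    permutation tests, motif occurrence near summits, promoter-proximal
    target assignment), nucleosome occupancy profiling from MNase-seq style
    tracks (nucleosome calling, peak classification, signal metaprofiles,
    induced differential occupancy with median-of-ratios normalization),
    and transcription-factor co-binding spacing analysis from position
    weight matrix localized sites. Includes a synthetic-data generator with
    planted ground truth so the full pipeline runs at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    IRanges,
    S4Vectors,
    GenomicRanges,
    Biostrings,
    rtracklayer,
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    DESeq2
Config/testthat/edition: 3
RoxygenNote: 7.3.3
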