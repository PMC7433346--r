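Package: TandemScan
Title: Detection and Breakpoint Inference of Tandem Duplications from
    Short-Read Alignments
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Detects tandem duplications (TDs) from coordinate-sorted
    short-read alignments in two stages. Per-bin read depth and mapping
    quality are GC-corrected, denoised with a total-variation penalized
    least-squares model and normalized to a common scale; bins whose
    (depth, quality) points fall in low-density regions of the 2D feature
    space are flagged as DBSCAN noise (with an exact k-d tree range
    search) and merged into rough TD regions. Boundaries are then refined
    to nucleotide resolution from soft-clipped split reads. Ships a
    read-level simulator that renders aligner-style BAM files with
    junction-spanning clipped reads for benchmarking, and evaluation
    utilities (sensitivity, precision, F1, boundary bias, overlap density
    score, permutation tests).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    GenomicRanges,
    GenomicAlignments,
    IRanges,
    S4Vectors,
    Rsamtools
Suggests:
    testthat (>= 3.0.0),
    quadprog,
    optparse,
    jsonlite
Config/testthat/edition: 3
biocViews: StructuralVariation, CopyNumberVariation, Sequencing,
    Clustering, Software
RoxygenNote: 7.3.3
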