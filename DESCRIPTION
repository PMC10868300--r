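Package: methylcnv
Title: Copy-Number Inference from DNA Methylation Array Intensities
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Infers copy-number variation profiles from Illumina-style DNA
    methylation array intensities. Combined methylated plus unmethylated
    probe intensities are tangent-normalized in log2 space against a panel
    of copy-number neutral controls, collapsed into fixed genomic bins with
    inverse-variance weights, segmented by weighted circular binary
    segmentation with permutation-calibrated change points, and screened
    for focal amplifications and homozygous deletions with sample-specific
    thresholds calibrated by a segmented block bootstrap. Includes cohort
    summarization into referential segments, SEG/BED interoperability, a
    synthetic-data generator with known copy-number ground truth, and a
    command-line wrapper.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    Rcpp,
    S4Vectors,
    IRanges,
    GenomicRanges,
    rtracklayer
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
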