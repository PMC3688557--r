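Package: chromintegrate
Title: Integrated Chromatin and Expression Analysis of Differentiation Time Courses
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end toolkit for integrating histone-mark ChIP-seq with
    microarray expression profiling of a differentiation time course. Provides
    generalized-log (glog) intensity calibration, empirical-Bayes moderated
    t-tests between the first and last time points, cross-species gene-set
    overlap statistics, a SICER-style window/gap Poisson island caller with
    input-chromatin background, position-weight-matrix motif enrichment with
    condition-swap background and a signed dual-mark statistic, nearest-TSS
    annotation, and a 16-state chromatin-change by expression-direction
    integration. Includes synthetic-data generators with recorded ground truth
    so every stage is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    cluster,
    jsonlite,
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    limma,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
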