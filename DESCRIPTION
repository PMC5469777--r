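Package: shallowCNV
Title: Copy Number Analysis for Shallow Whole-Genome Sequencing of Few-Cell Samples
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Read-depth copy-number analysis for shallow (~0.3x) whole-genome
    sequencing of single- and few-cell whole-genome-amplified (WGA) samples.
    Bins the genome into fixed-size windows, corrects GC-content and
    mappability bias by stratified median scaling, median-normalizes read
    counts into copy-number estimates, segments the log2 ratio track with
    circular binary segmentation using a permutation-calibrated two-sample
    t-statistic, and calls gains and losses against a +/-0.35 log2 threshold
    with a minimum-consecutive-window rule. Includes a per-sample read-count
    variance statistic for quality gating of failed amplification profiles,
    true/false-positive evaluation of call sets against a reference
    karyotype, one-way ANOVA across amplification-method groups, and a
    synthetic count simulator that emulates multiplicative amplification
    representation bias for full cohort designs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    ggplot2,
    jsonlite,
    stats,
    utils,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
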