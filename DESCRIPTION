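Package: rdnacopy
Title: Relative 45S rDNA Copy Number and CpG Methylation Coupling from
    Read Depth
Version: 0.1.0
Authors@R:
    person("rdnacopy", "authors", email = "rdnacopy@example.org",
           role = c("aut", "cre"))
Description: Estimates relative 45S ribosomal DNA copy number from per-base
    read depth of whole-genome (bisulphite or standard) sequencing, using a
    modified 45S reference and single-copy exon/intron background regions for
    normalization. Selects depth-stable 150-bp quantification windows by a
    sliding-window coefficient-of-variation scan, computes upper-tail-trimmed
    background read depth, aggregates CpG methylation into 200-bp bins with
    coverage filters, and tests the coupling between copy number and bin-level
    methylation with covariate-adjusted linear models and Benjamini-Hochberg
    false discovery rate control. Ships a synthetic cohort generator with
    known ground truth (lognormal copy number, negative-binomial depth noise,
    smooth positional coverage profiles, library-chemistry bias, and a
    copy-number-coupled methylation model) plus binomial depth thinning for
    coverage-robustness checks.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
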