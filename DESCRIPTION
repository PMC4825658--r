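Package: barseqscreen
Title: Pooled FACS Reporter Screens Analyzed by Barcode Sequencing
Version: 0.1.0
Authors@R: person("Screen", "Tools", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Analysis and simulation of pooled reporter-gene screens in
    barcoded knockout libraries read out by barcode sequencing (Bar-Seq).
    Provides UPTAG/DNTAG barcode catalogs and concatenated references,
    FASTQ demultiplexing and Hamming-distance barcode counting with full
    read ledgers, a negative-binomial conditioned exact test of mutant
    enrichment in FACS-sorted pools against the presorted library with
    median-of-ratios normalization and method-of-moments dispersion
    estimation, phenotype classification across sorted pools,
    concordance-at-the-top (CAT) comparison of ranked gene lists with a
    hypergeometric null band, flow-cytometry summaries (median fold
    changes, two-component mixture fits for bimodal subpopulations), and
    a full synthetic-screen generator with ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    Biostrings
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
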