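Package: cuedit
Title: Calling and Trans-Regulator Screening of Plant Organellar C-to-U RNA Editing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An analysis toolkit for cytidine-to-uridine (C-to-U) RNA editing
    in plant organellar transcripts. Calls editing sites from per-position
    base-count (pileup-derived) tables with depth and level filters,
    characterises the sequence context of edited cytidines and their codon
    consequences, tests whether edited positions avoid base-paired (double-
    stranded) RNA regions using a base-pair-maximisation local fold, resolves
    allele-specific editing in interspecies hybrids, and screens for candidate
    trans-regulators by exact-permutation Spearman correlation between
    per-site editing levels and genome-wide expression (RPKM) with
    Benjamini-Hochberg FDR control. A synthetic-data generator reproduces the
    statistical structure the analysis assumes (5-prime-base-dependent levels,
    structure avoidance, regulator-coupled levels across root and shoot
    replicates, diverged parental alleles), so the full pipeline is testable
    without external sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
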