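Package: widcfoc
Title: Cell-Free DNA Methylation Scoring for Ovarian Cancer Detection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Targeted bisulfite sequencing analysis of plasma cell-free DNA
    methylation for ovarian cancer detection. Simulates amplicon panels,
    case-control cohorts, bisulfite read pairs and fragment-size profiles;
    performs reduced-alphabet bisulfite alignment, read-level CpG methylation
    calling and per-region fully-methylated-read percentages; calibrates
    per-region thresholds at a target specificity and computes the WID-cfOC
    score, CA125 classification with temporal imputation, and the combined
    score; quantifies genomic DNA contamination from fragment-size profiles
    with a cohort-median split; and evaluates sensitivity and specificity with
    exact Clopper-Pearson intervals, empirical ROC curves, paired-difference
    t-intervals, stratified diagnostics, and day/night concordance.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    rtracklayer,
    jsonlite,
    stats,
    utils
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
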