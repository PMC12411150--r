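Package: shallowCNA
Title: Chromosomal Instability Profiling from Low-Coverage Whole-Genome
    Sequencing Bin Counts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Detects somatic copy-number alterations and calls per-sample
    chromosomal instability (CIN) from shallow whole-genome sequencing.
    Read counts in fixed-width genomic bins are normalized against a
    control cohort (per-bin Z-scores and log2 copy ratios), gated by an
    adjacent-bin noise statistic, segmented with an original circular
    binary segmentation implementation using permutation significance,
    and summarized into gain/loss calls, chromosome-arm frequencies and
    gene-level events. Includes a negative-binomial cohort simulator
    with planted copy-number events and ground truth, an ungapped
    mismatch-tolerant microbial read screen, and contingency-table
    statistics for cohort stratification.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    jsonlite,
    Rcpp,
    Biostrings
LinkingTo: Rcpp
Suggests:
    Rsamtools,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
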