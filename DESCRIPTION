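Package: svrscan
Title: Scan-Statistic Detection of Structurally Variable Regions in RNA
    Structure Probing Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Normalization and nucleotide-resolution differential analysis of
    RNA structure probing (SHAPE, icSHAPE, DMS-seq) reactivities measured in
    two cellular conditions.  Reactivities are winsorized, quantile normalized
    within conditions, and anchored between conditions with a robust
    (Huber M-estimate) log-linear fit on a structurally invariant pivot set.
    Transcripts are then scanned with variable-length windows: positional
    two-sided Wilcoxon rank-sum p-values are aggregated into a scan statistic
    whose significance is calibrated by Monte-Carlo sampling under a uniform
    null, controlling the family-wise error rate of the reported structurally
    variable regions (SVRs).  Includes a conformation-mixture simulator of
    two-condition reactivities with known ground-truth SVRs, negative-control
    construction by replicate splitting, and interval-level evaluation metrics
    (Jaccard index, average distance, precision/recall, specificity, false
    positive rate).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    generics,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    MASS,
    limma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
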