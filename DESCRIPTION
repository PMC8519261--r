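Package: ctxpls
Title: Imaging Transcriptomics of Cortical Thickness Changes via Partial
    Least Squares
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Links regional gene expression in the healthy cortex to regional
    cortical-thickness statistics in a patient cohort. Maps point expression
    samples with stereotactic (MNI) coordinates onto a labelled cortical
    parcellation with a millimetre tolerance, builds a region-by-gene
    predictor matrix by two-level (within-donor, then across-donor)
    averaging, computes regional Welch t-statistics of group differences in
    cortical thickness and t-statistics of region-wise regressions of
    thickness on clinical scores (both with Benjamini-Hochberg correction),
    fits single- and multi-response partial least squares (NIPALS) models
    with leave-one-out component selection, and tests gene sets for
    enrichment in the ranked PLS gene weights with a weighted running-sum
    statistic and a gene-permutation null. Ships a synthetic-data generator
    with planted spatial expression gradients, group effects and clinical
    couplings so the full pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    mixOmics,
    fgsea,
    withr
Config/testthat/edition: 3
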