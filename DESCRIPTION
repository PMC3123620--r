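Package: mirct
Title: miRNA Expression Signatures from Paired qPCR-Array Ct Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for deriving and validating microRNA expression
    signatures from paired (malignant / adjacent-normal) qPCR-array cycle-threshold
    (Ct) data: Ct-scale quantile normalization, paired Student's t and Wilcoxon
    signed-rank differential-expression testing with Benjamini-Hochberg correction,
    threshold-based signature selection, hierarchical-clustering-based sample
    classification with majority-vote scoring, resampling cross-validation of
    signature generality with a permuted-label null, and PCA-based subgroup
    discovery among malignant samples. A synthetic-data generator emulates the
    paired-cohort Ct structure so every stage is testable without laboratory data.
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
    withr,
    limma,
    knitr,
    rmarkdown
Config/testthat/edition: 3
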