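Package: radtex
Title: Mask-Aware 2D Radiomic Texture Analysis for Tumor-Edema Discrimination
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Extracts first-order (histogram and absolute-gradient),
    second-order (gray-level co-occurrence matrix, GLCM) and higher-order
    (gray-level run-length matrix, GLRLM) texture features from masked 2D
    regions of interest in MR images, with optional 1%-99% percentile
    intensity normalization.  Implements a two-reader radiomics workflow
    for discriminating brain tumor from peritumoral edema: per-reader
    L1-penalized (LASSO) logistic feature selection with cross-validated
    penalty, cross-reader consensus, ROC/AUC evaluation with DeLong
    confidence intervals, perfect-classification threshold discovery and
    Cohen's kappa inter-rater agreement.  Includes a synthetic cohort
    generator that emulates the two-tissue, two-reader, multi-sequence
    study design so the whole pipeline is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    glmnet,
    pROC,
    jsonlite,
    RNifti,
    EBImage,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    e1071,
    withr
Config/testthat/edition: 3
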