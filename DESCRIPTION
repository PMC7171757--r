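Package: radsurv
Title: Radiomic Texture Features and Random Survival Forest Modelling for
    Chemoradiotherapy Outcomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end radiomics survival pipeline for node-positive cervical
    cancer treated with definitive chemoradiotherapy. Extracts 3-D histogram,
    shape and texture features (GLCM, GLRLM, NGLDM, GLZLM) from segmented
    tumour and lymph-node regions of interest on two co-registered MR
    sequences, reduces dimensionality by Spearman-correlation hierarchical
    clustering, ranks features by bootstrap-aggregated penalized Cox
    regression, fits random survival forests per endpoint (local control,
    regional control, distant metastasis-free survival, overall survival), and
    evaluates models with Harrell's C-index, IPCW time-dependent ROC,
    maximally selected log-rank cutpoints and Kaplan-Meier risk groups. A
    synthetic dual-sequence cohort generator with texture-driven hazards makes
    every stage testable without patient data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    glmnet,
    jsonlite,
    ranger,
    Rcpp,
    RNifti,
    stats,
    survival,
    utils
LinkingTo:
    Rcpp
Suggests:
    pheatmap,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
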