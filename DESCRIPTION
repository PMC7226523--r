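Package: radprog
Title: Radiomic Texture Signatures for Survival and Recurrence Prognosis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for radiomics-based outcome modeling of 3-D tumor images.
    Generates synthetic contrast-CT-like tumor phantom cohorts with planted
    texture-outcome signal, extracts an 841-feature radiomic panel (shape,
    first-order, GLCM, GLDM, GLRLM, GLSZM and NGTDM texture classes on the
    original image and on eight undecimated 3-D wavelet sub-bands, following
    Imaging Biomarker Standardization Initiative definitions), performs a
    resampled three-step feature selection (univariate Cox or ANOVA screen
    with false-discovery-rate control, recursive correlation pruning, and
    sequential floating forward selection), fits gradient-boosted Cox and
    logistic ensembles under nested cross-validation, and compares clinical,
    radiomic and combined prognostic models by concordance index, AUC and
    AUPRC, with Kaplan-Meier risk stratification and two-way hierarchical
    clustering of the feature matrix.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    survival,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    jsonlite,
    yaml,
    RNifti
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
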