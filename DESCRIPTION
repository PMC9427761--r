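Package: ringomics
Title: Peritumoral-Ring Radiomics Signatures for Tumor Immune Microenvironment Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds and evaluates CT radiomics signatures of the tumor immune
    microenvironment from paired intratumoral and peritumoral regions of
    interest. Provides seeded synthetic CT phantom cohorts with planted
    texture structure, peritumoral ring construction via anisotropic signed
    Euclidean distance transforms, an IBSI-style feature pool (first-order,
    shape, GLCM, GLRLM and NGTDM features over multiple discretizations),
    mRMR plus cross-validated LASSO signature fitting with tertile-based
    risk groups, and downstream evaluation by ROC/AUC, Kaplan-Meier,
    log-rank, Cox regression, Harrell's C-index, nomogram linear predictors
    and treatment-response tables.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    Rcpp,
    RNifti,
    glmnet,
    survival,
    pROC,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    withr,
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
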