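Package: usradiomics
Title: Ultrasound Radiomics Signatures for Lymph Node Metastasis Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: An end-to-end B-mode ultrasound radiomics pipeline for
    predicting lateral cervical lymph node metastasis from the primary
    tumor in papillary thyroid carcinoma. Reads grayscale images and
    binary tumor masks, normalizes and quantizes the region of interest,
    extracts a 730-feature vector (first-order histogram statistics,
    gray-level co-occurrence and run-length matrix features, each on the
    original patch and on four single-level Haar wavelet subbands),
    selects features with cross-validated LASSO logistic regression,
    computes a per-patient radiomics score, and evaluates discrimination
    with ROC/AUC (DeLong confidence intervals) and cohort-comparison
    statistics. Includes a synthetic speckle-image cohort generator so
    the whole pipeline is testable without patient data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    tools,
    utils,
    glmnet,
    jsonlite,
    png,
    jpeg
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
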