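Package: seromics
Title: Serum Autoantibody Seromics Screening and Committee Neural Network
    Classification for Liver Cancer
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for protein-microarray based serum autoantibody (AAb)
    biomarker discovery in hepatocellular carcinoma (HCC). Provides a
    synthetic seromics cohort generator (spot-level array scans with
    duplicate spots, two detection channels, clinical metadata including
    alpha-fetoprotein, HBsAg and BCLC stage); spot-level signal-to-noise
    quantification and cross-array normalization; discovery- and test-phase
    marker screening with positive-ratio and sensitivity-at-specificity
    criteria; consensus predictor selection by stepwise logistic regression
    inside 10-fold cross-validation; a committee-vote feedforward neural
    network classifier trained over repeated k-fold splits; and ROC-based
    evaluation of the classifier against and in combination with AFP,
    stratified by AFP status, HBsAg status and tumor stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    jsonlite,
    limma,
    stats,
    utils,
    withr,
    yaml
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
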