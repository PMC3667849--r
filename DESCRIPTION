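Package: carcinopath
Title: Pathway-Based Prediction of Chemical Hepatocarcinogenicity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts long-term liver carcinogenicity of chemicals from
    short-term (90-day) gene expression data using network-structured
    pathway enrichment features. Pathways are treated as directed graphs of
    interacting gene products; a structurally enhanced enrichment statistic
    weights genes by topological position and rewards clustered
    perturbation, with significance calibrated by gene-label permutation
    and converted to z-score features. A survival-adjusted poly-3 tumor
    statistic provides the continuous carcinogenicity target, which is
    related to the pathway features by a super-learner ensemble with
    nested (honest) cross-validation. Includes cross-species orthologous
    pathway panels for extrapolated predictions, ROC/operating-point and
    dose-response evaluation, and a synthetic-data generator with known
    ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    limma,
    randomForest,
    e1071,
    glmnet,
    pracma,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    jsonlite
Config/testthat/edition: 3
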