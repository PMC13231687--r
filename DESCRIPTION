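Package: acprofiles
Title: Activity Cliff Compound Prediction from Bioactivity Profiles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Extraction of matching molecular series and assay-wise activity
    cliffs from binary compound-profiling matrices, and leakage-controlled
    machine-learning experiments that predict the activity state of activity
    cliff compounds from bioactivity profiles, structural fingerprints
    (ECFP4), or their combination. Includes assay Tanimoto similarity and
    similarity-based profile reduction, a 1-nearest-neighbor assay label
    transfer baseline, random forest / gradient boosting / support vector
    machine classifiers with grid-search cross-validation, mean decrease in
    impurity feature importance, balanced accuracy / MCC / ROC-AUC
    evaluation with paired Wilcoxon testing, and a synthetic analog-series
    and profiling-matrix generator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ChemmineR,
    ChemmineOB,
    randomForest,
    xgboost,
    e1071,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
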