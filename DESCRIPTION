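Package: mbrisk
Title: Markov-Boundary Feature Selection and Nested Cross-Validated Risk
    Prediction for Rare Binary Outcomes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Implements an end-to-end analysis pipeline for predicting a
    rare binary clinical outcome from a modest tabular cohort: missingness
    filtering, unsupervised k-nearest-neighbour imputation and 0-1
    normalization; semi-interleaved HITON-PC local causal (parents-and-
    children) feature selection driven by G-squared and Fisher-z
    conditional-independence tests; repeated nested N-fold cross-validation
    with inner-loop model selection across seven classifier families
    (linear, polynomial and RBF support vector machines, random forest,
    lasso, logistic regression, and stepwise logistic regression) scored by
    AUC; label-shuffling permutation tests for overall predictive signal
    and protocol bias; bootstrap stability ranking of selected variables;
    and a synthetic cohort generator with planted causal structure for
    validating every stage against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    e1071,
    randomForest,
    glmnet,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
RoxygenNote: 7.3.3
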