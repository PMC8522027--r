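Package: receptex
Title: Extraction of Breast Cancer Receptor Status from Bilingual Pathology Reports
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Machine-learning pipeline for extracting estrogen receptor (ER),
    progesterone receptor (PR) and HER2 (immunohistochemistry and in-situ
    hybridization) status from free-text Dutch and French breast pathology
    reports, as processed by population-based cancer registries. Provides
    report pre-processing (line, sentence and word segmentation with character
    offsets), a bilingual concept lexicon of regular expressions, biomarker
    segment isolation, seven families of numeric features (regex presence and
    counts, match locations, clinical numeric values, word counts, Jaccard
    similarities to reference sentences, Boolean combinations and meta
    logistic scores), feature selection by L1-regularized multinomial logistic
    regression, a grid of classical classifiers (random forests, support
    vector machines, regularized multinomial logistic regression, decision
    trees, k-nearest neighbors) with optional self-training, model selection
    and evaluation by macro-averaged F1, a regex rule-based baseline, and a
    configurable synthetic report generator that reproduces the documented
    heterogeneity of registry corpora so the whole pipeline can be trained and
    audited without confidential data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stringi,
    jsonlite,
    glmnet,
    randomForest,
    e1071,
    rpart,
    class,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
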