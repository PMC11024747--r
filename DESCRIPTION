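Package: rehabext
Title: Extraction of Physical Rehabilitation Exercise Information from Clinical Therapy Notes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for mining physical-rehabilitation exercise information from
    the free text of clinical therapy notes. Ships a 101-concept clinical
    ontology (type of motion, laterality, body location, plane of motion,
    duration, sets and reps, exercise purpose, exercise type, body position)
    with surface-form lexicons; note filtering, therapeutic-procedures section
    extraction and category-enrichment scoring; a rule-based concept tagger
    with exercise-status resolution (in-office, home exercise program, not
    performed) and numeric duration/sets/reps parsing; per-concept
    bag-of-words classifiers (logistic regression, polynomial SVM, AdaBoost,
    gradient boosting); auto-generated zero- and few-shot yes/no prompts for
    chat-model backends with a deterministic offline mock; a synthetic
    therapy-note generator with gold-standard labels; and an evaluation
    harness (span-, sequence- and numeric-level precision/recall/F1, Fleiss
    kappa, stratified train/test splitting).
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    yaml,
    jsonlite,
    Matrix,
    glmnet,
    e1071,
    xgboost,
    rpart,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
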