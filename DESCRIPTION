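Package: tiabscreen
Title: Automated Title and Abstract Screening with Likert-Scored Relevance Prompts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for fully automated title-and-abstract screening of
    citation corpora in systematic literature reviews. Builds structured
    relevance-scoring prompts (instruction, title, abstract, relevant
    criteria), sends them to a pluggable text-generation backend, extracts
    Likert relevance scores from the answers, and turns the scores into
    include/exclude classifiers by thresholding. Includes the complete
    evaluation machinery (sensitivity, specificity, accuracy, precision,
    F1, threshold-swept ROC curves with AUC, invalid-response accounting),
    a keyword-derivation preprocessing step with a simple unsupervised
    topic-model baseline screener, a deterministic mock backend so the
    whole pipeline is testable offline, and a synthetic corpus generator
    with controllable prevalence and a plantable lexical signal.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
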