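Package: hearbn
Title: Discrete Bayesian Network Modelling of Occupational Hearing Loss
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing noise-induced hearing loss in worker cohorts.
    Computes the monaural and binaural "social" hearing-loss percentage indices
    from pure-tone audiometric thresholds (500-3000 Hz), discretizes loss, age
    and family history into standard epidemiological groups, and fits a
    discrete Bayesian network over gender, age group, family history and loss
    group. Includes exact inference by variable elimination, BIC hill-climbing
    structure learning, ancestral sampling, scenario (sensitivity) tables of
    conditional loss-group distributions, ten-fold cross-validated one-vs-rest
    ROC/AUC, and a seeded synthetic-cohort generator calibrated to published
    cohort summary tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    graphics,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    optparse
Config/testthat/edition: 3
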