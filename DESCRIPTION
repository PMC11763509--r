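Package: tkipolicy
Title: Reinforcement-Learning Treatment Recommendation for EGFR-Mutant NSCLC
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Offline reinforcement-learning pipeline recommending the line and
    generation of the first tyrosine kinase inhibitor (TKI) for advanced
    non-small cell lung cancer with EGFR mutations. Provides a seeded
    synthetic-cohort generator with a planted treatment effect, inclusion
    filtering and clinical feature engineering (log neutrophil-to-lymphocyte
    ratio, four-level action coding, one-year progression category), SMOTE
    minority oversampling, an extremely-randomized-trees feature screen, and
    a one-step deep Q-network trained with Boltzmann exploration and shaped
    rewards. The fitted Q-function is a classed model object with methods
    for per-action Q summaries, action frequencies by treatment line,
    partial dependence, a policy AUC, and single-patient recommendations.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    jsonlite,
    pROC,
    ranger,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
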