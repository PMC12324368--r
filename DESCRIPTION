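Package: optoshift
Title: Simulation and Analysis of Evidence Coding Under Striatal Pathway Inhibition
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to simulate and analyse an accumulation-of-evidence
    virtual T-maze experiment with unilateral optogenetic inhibition of the
    striatal direct or indirect pathway. Provides a task generator (spatial
    Poisson cues with a refractory window, closed-loop side debiasing, a
    multi-state GLM-HMM behavioural agent, laser scheduling), a synthetic
    spike-train generator for evidence-, choice- and outcome-tuned neural
    populations with pathway-specific laser modulation, GLM-HMM fitting with
    cross-validated model comparison and state assignment, per-neuron linear
    encoding models with permutation-null tuning classification, per-position
    lasso evidence-decoding axes with nested cross-validation and PC1 control
    axes, linear mixed-effects tests of laser-induced coding shifts, and the
    four generative hypothesis models linking evidence-tuned neurons,
    choice-tuned neurons, laser and action, together with estimators that
    recover their parameters.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    glmnet,
    jsonlite,
    lme4,
    lmerTest,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
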