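Package: pelearn
Title: Reinforcement-Learning Model-Based fMRI Analysis of Reward and
    Punishment Prediction Errors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Implements a complete analysis pipeline for a probabilistic
    instrumental learning task with gain, loss and neutral conditions:
    Q-learning agents with softmax choice, subject-level maximum-likelihood
    fitting with chance-model comparison, fixed-learning-rate prediction-error
    series for model-based fMRI, ROI-level GLMs with hemodynamic-response
    convolved parametric modulators, generalized psychophysiological
    interaction (gPPI) connectivity with a seed region, and the group-level
    statistics used in reinforcement-learning studies of depression
    (mixed-effects learning-curve models, mixed-design ANOVAs with partial
    eta squared, Cohen's ds, partial correlations, Fisher z comparisons,
    Bonferroni thresholds). A synthetic-cohort generator with planted group
    effects provides ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    lme4,
    lmerTest,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
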