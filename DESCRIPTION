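Package: rlwaves
Title: Hierarchical Bayesian Modelling of Longitudinal Probabilistic
    Reinforcement Learning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Generative heuristic (win-stay, win-stay-lose-shift) and
    Rescorla-Wagner value-based models for a two-choice probabilistic
    feedback task learned at two longitudinal waves, with hierarchical
    Bayesian estimation that links the same parameter across waves
    through a correlated subject-level structure. Includes a synthetic
    two-wave cohort generator, model-free behavioral summaries,
    PSIS-LOO model comparison with pseudo-BMA+ weights, one-step-ahead
    posterior predictions, parameter and model recovery studies, and
    simulation-based mapping of the optimal learning rate and inverse
    temperature for the task.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr
Config/testthat/edition: 3
NeedsCompilation: yes
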