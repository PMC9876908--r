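Package: twostep
Title: Model-Based and Model-Free Reinforcement Learning on the
    Two-Stage Markov Decision Task
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulation and likelihood-based fitting of model-free (SARSA),
    model-based (FORWARD) and HYBRID reinforcement-learning agents on a
    sequential two-choice Markov decision task with 70/30 probabilistic
    transitions and monetary outcomes. Provides blockwise maximum a
    posteriori estimation with beta/gamma priors and carryover of values
    and parameters across 40-trial blocks, fixed-effects group fitting,
    BIC model comparison, Spearman parameter-correlation and
    parameter-recovery diagnostics, social value orientation (SVO) slider
    scoring and group classification, descriptive behavioral metrics
    (moving-average reward, reaction-time block summaries split by
    transition type), a model-based versus model-free simulation study
    with an origin-constrained sigmoid learning-speed statistic, and a
    synthetic-cohort generator so the whole pipeline is testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    graphics,
    lhs,
    stats,
    utils,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
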