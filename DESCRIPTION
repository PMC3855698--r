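Package: dyadRL
Title: Reinforcement Learning Models of Dyadic Perceptual Decisions
Version: 0.1.0
Authors@R:
    person("dyadRL", "Maintainers", email = "maintainers@dyadrl.example.org",
           role = c("aut", "cre"))
Description: Simulation and model fitting for collective perceptual
    decision making in dyads that share confidence ratings. Provides a
    seeded generator for two-interval forced-choice sessions with
    signal-detection observers, quantized signed confidence and a
    configurable confidence-escalation drift; cumulative-Gaussian
    (probit) psychometric fitting with slope and collective-benefit
    ratios; a single-step temporal-difference learner over reduced
    confidence-pair states with a greedy, confidence-tie-breaking
    policy; learning-rate grid search under accuracy-maximizing and
    similarity-maximizing objectives with binned learning restarts; and
    confidence-escalation summaries correlated with model collective
    benefit. Includes a command-line interface for end-to-end
    reproducible synthetic cohorts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
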