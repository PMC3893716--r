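Package: riskshift
Title: Simulation and Analysis of Reward-Shift and Risky-Choice Operant Behavior
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for studying asymmetric reward learning in two-alternative
    operant tasks. Simulates full session protocols (Pavlovian conditioning,
    baseline lever pressing, mid-session reward upshifts and downshifts, and
    risky-versus-safe choice under variable reward schedules) with
    reinforcement-learning agents whose learning rates differ for positive and
    negative prediction errors. Computes block-normalized side preferences, the
    learning-bias score contrasting upshift and downshift switching speed,
    risky-choice scores, and the accompanying statistical battery (mixed
    factorial ANOVA with subject error strata, pooled-variance t tests, and
    Pearson correlation), and orchestrates end-to-end in-silico replications
    with reproducible seeded cohorts.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
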