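Package: critdyn
Title: Dynamic Decision-Criterion Models for Yes-No Detection Tasks
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for modelling trial-by-trial dynamics of the decision
    criterion in yes-no signal detection tasks. Implements a generative
    model in which the criterion is shifted by a fixed amount after each
    trial outcome (hit, miss, false alarm, correct rejection) and decays
    geometrically toward a resting value; a semi-analytical Markov solver
    that discretises the criterion axis and computes stationary criterion
    distributions, including for sessions with alternating easy/hard
    stimulus blocks; maximum-likelihood fitting of the model to decision
    sequences by stochastic gradient ascent, and a brute-force grid fit in
    ROC space for the decay-free variant; session simulation for three
    experimental formats (alternating blocks, randomised levels, randomised
    levels with correction trials); and the accompanying descriptive
    analyses (bias-free proportion correct, sigmoid psychometric fits,
    block-position wrapping with shared-decay exponential regression, and
    ROC markers conditioned on the previous trial's outcome).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    Matrix,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
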