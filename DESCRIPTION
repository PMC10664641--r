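Package: nichegoal
Title: Niche-Based Breeding Goal Optimization and Desired-Gain Selection Indices
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Models the environments and niches of domestic animal breeds as
    distributions over owner desires and influencing variables, evaluates
    owner/producer/consumer merit functions and the resulting adaptedness of a
    breed to its niche (in closed form under Gaussian phenotypes or by Monte
    Carlo), recovers merit-function parameters from simulated discrete-choice
    experiments by maximum likelihood, maximizes adaptedness over the set of
    permissible breeding goals (search area intersected with the multi-trait
    response ellipsoid), derives the corresponding desired-gain selection
    index, and simulates the breeding program to check goal validity against a
    minimum viable population size.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    MASS,
    jsonlite,
    pracma,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
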