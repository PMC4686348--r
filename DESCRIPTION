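Package: bsscult
Title: Blind Source Separation Analysis of Evoked Activity in Neural Cultures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to study how networks driven by probabilistic mixtures of two
    hidden binary sources come to separate them. Provides a synthetic
    microelectrode-array culture simulator (Bernoulli sources, mixed binary
    stimulation, linear-rate Poisson responses, state-dependent Hebbian
    plasticity), spike detection and evoked-count preprocessing for raw voltage
    traces, per-electrode conditional response statistics and Poisson
    Kullback-Leibler divergence tracking, maximum-likelihood estimation of
    population connectivity with a variational free-energy decomposition
    (internal energy, entropy, free energy), and closed-form estimation of
    Hebbian and state-dependent Hebbian learning efficacies compared by BIC.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    signal,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
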