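Package: hergfit
Title: Bayesian Fitting of a hERG Channel Markov Model to Voltage-Clamp Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulates a four-state Markov model of the rapid delayed-rectifier
    potassium current (IKr, carried by hERG channels) under arbitrary
    voltage-clamp protocols, and infers its nine parameters from recorded
    current traces. Model, protocol, data and fitting algorithm are bound
    together through a machine-readable JSON fitting specification with
    box-uniform priors and physiological rate constraints. Inference uses
    multi-start CMA-ES global optimisation to seed an adaptive-covariance
    Metropolis MCMC sampler under a Gaussian likelihood, and reports maximum
    posterior density estimates, marginal posterior histograms, credible
    intervals and identifiability diagnostics. A synthetic-data module
    generates fully reproducible fixture datasets with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    graphics,
    deSolve,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
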