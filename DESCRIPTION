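Package: aoncb
Title: Subthreshold Moment Analysis of Conductance-Based Neurons Driven by
    Synchronous Synaptic Inputs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for the all-or-none-conductance-based (AONCB) neuron model
    driven by correlated compound-Poisson synaptic input. Provides correlated
    activation-pattern (synchrony) models including the beta-binomial pool and
    calibrated mixtures with prescribed within- and across-neuron spiking
    correlations; exact event-driven Marcus simulation of feedforward neuronal
    populations and an exponential integrator for finite synaptic timescales;
    an exact stationary moment engine (mean, covariance, third and arbitrary
    mixed moments) based on a PASTA fixed-point analysis; closed-form
    small-weight approximations for voltage variance, cross-neuron correlation
    and skewness; and empirical estimators, PASTA validation and desk-scale
    parameter sweeps.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    yaml
Config/testthat/edition: 3
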