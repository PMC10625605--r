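Package: neurosampler
Title: Sampling-Based Bayesian Inference in Recurrent Spiking Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Simulates recurrent networks of Poisson spiking neurons whose
    spike-generation variability produces samples from posterior
    distributions over latent stimuli, with recurrent synaptic weights
    encoding the prior. Provides the Gaussian generative models on a ring
    (hierarchical stimulus/stimulus-parameter and parallel two-stimulus),
    their analytic posteriors, reference Gibbs samplers, an excitatory-only
    linear sampling network, a full excitatory-inhibitory Hawkes-process
    ring network, coupled circuits for multivariate posteriors, population
    vector decoders, and information-theoretic diagnostics (Gaussian KL
    divergence, mutual-information bounds, bias-corrected linear Fisher
    information, differential noise correlations, Fano factors, recurrent
    weight scans).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
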