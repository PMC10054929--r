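Package: likewire
Title: Like-to-Like Wiring Analysis for Functional Connectomics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for testing like-to-like wiring rules in functional
    connectomics data: axon-dendrite co-travel distance (Ld) from neuron
    skeletons, anatomical control cohorts, functional similarity metrics
    (signal correlation, feature-weight cosine similarity, receptive-field
    center distance, orientation tuning), Tweedie and Poisson regression
    models separating axonal-scale from synaptic-scale selectivity, a
    common-input statistic (rho) contrasting observed postsynaptic-cohort
    similarity with the expectation under a purely pairwise rule, and a
    small recurrent-network simulation in which like-to-like connectivity
    emerges with training. Includes a synthetic-data generator with planted,
    recoverable ground truth so the full pipeline is testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    mgcv,
    glmmTMB,
    yaml
Suggests:
    testthat (>= 3.0.0),
    emmeans,
    jsonlite,
    knitr
Config/testthat/edition: 3
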