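Package: cfareact
Title: Reactivation Analysis of Amygdala Flavour Representations During
    Delayed Malaise
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for chronic extracellular recordings from
    the central amygdala (CEA) during conditioned flavour aversion
    learning, in which a novel flavour is followed, after a delay, by
    visceral malaise (CGRP neuron stimulation or LiCl injection). The
    package bins and normalizes spike trains, classifies neurons as
    flavour-preferring, water-preferring or nonselective with a rank-sum
    test under two-stage Benjamini-Krieger-Yekutieli FDR control, builds
    peri-event time histograms, trains an L1-penalized multinomial
    logistic decoder on consumption activity and detects reactivation
    events from its posterior during delay and malaise, projects
    population activity onto PCA trajectories with cross-day frozen
    loadings, relates stimulation-period responses to cross-day
    plasticity of flavour responses, fits a diagonal-covariance Gaussian
    mixture over stimulation response types, and debleaches GCaMP/AKAR2
    fibre-photometry traces. A synthetic-session generator with ground
    truth makes every stage testable without recorded data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    signal,
    yaml
Suggests:
    testthat (>= 3.0.0),
    glmnet,
    mclust
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
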