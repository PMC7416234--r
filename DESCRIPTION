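Package: mipso
Title: Channel and Feature Selection for Motor-Imagery BCI with Multilevel Binary PSO
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Signal-processing toolkit for two-class motor-imagery
    brain-computer interfaces. Extracts power-spectral-density features from
    multichannel trials with a modified Stockwell transform (frequency-scaled
    Gaussian window with tunable width), classifies them with a Bayesian
    linear discriminant whose regularization is set by evidence maximization,
    and selects channels and/or features with a multilevel binary particle
    swarm optimizer wrapped around the classifier. Includes a synthetic
    two-class oscillatory trial generator with planted informative channels,
    a full evaluation-metric suite (Cohen's kappa, F-score, sensitivity,
    specificity, precision), plain-text I/O for trials, features, masks and
    models, and ggplot2 visualisations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
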