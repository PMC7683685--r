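Package: dynforce
Title: Force Spectroscopy of Motor-Microtubule Unbinding Under Constant Pulling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of single-molecule optical-tweezers
    constant-pulling assays for motor-protein-microtubule bonds. Provides a
    stochastic simulator of a bead in a harmonic trap pulled by a sweeping
    stage through a compliant motor linkage, rupture-event detection with a
    primary-event filter, conversion of unbinding-force distributions into
    compliance-corrected force-dependent unbinding rates via kernel density
    estimation, bootstrap confidence intervals and a shifted-null bootstrap
    difference-of-means test, and classification of stalk-helix registries
    (alpha/beta/gamma) and bond phenotypes (slip, ideal, catch and piecewise
    combinations) from the estimated rate curves.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    jsonlite,
    generics,
    withr,
    stats,
    graphics,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
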