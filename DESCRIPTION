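Package: evnest
Title: Expected-Value Estimation for Mass-Action Reaction Networks by Nested Sampling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Estimates prior-averaged expected values of simulation objectives
    (end-point PARP cleavage, per-pathway caspase-activation flux) for
    mass-action ODE reaction networks by nested-sampling integration over
    log10-uniform kinetic-parameter priors. Ships a reduced extrinsic-apoptosis
    reaction network together with its six in-silico knockout subnetworks,
    regulator-scan drivers, expected-value ratios, crossing and peak detection,
    and a precision-versus-cost study, with tidy tabular outputs and ggplot2
    visualisations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    stats,
    utils,
    tools,
    tibble,
    dplyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    yaml,
    xml2
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
NeedsCompilation: yes
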