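Package: pipgate
Title: PIP2-Dependent Gating Kinetics of DAG-Activated TRPC Channels
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Kinetic modeling and trace analysis of phosphoinositide-dependent
    gating in diacylglycerol-activated TRPC6/7 channels. Implements a tetrameric
    PIP2-occupancy Markov gating model with supportive and inhibitory coupling
    polarities, ODE models of voltage-sensitive phosphatase (VSP) lipid depletion
    and receptor-PLC signaling, a synthetic whole-cell patch-clamp and FRET trace
    generator, the logistic-decay / exponential-recovery / Hill dose-response
    fitting pipeline used to quantify PIP2 depletion experiments, and a
    many-to-one mutant screening stage with resampling-based Dunnett comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    deSolve,
    minpack.lm,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    jsonlite,
    yaml,
    ggplot2,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
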