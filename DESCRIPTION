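Package: dualadapt
Title: Perceptron-Gain Modelling and Analysis of Dual Prism Adaptation
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulates dual visuo-motor ('prism') adaptation with a minimal
    perceptron-gain neural network: a Gaussian population code for target
    angle is read out through nonnegative spatial weights and a cue-gated
    multiplicative gain, and both are adapted by a weight-perturbation
    reinforcement rule that implements stochastic gradient descent on the
    pointing error. Includes an exact gradient-descent oracle, pre-training
    of the normal visuo-motor mapping, alternating adaptation/re-adaptation
    schedules with ensemble simulation, the behavioural analysis pipeline
    (baseline correction, direct-effect and aftereffect extraction,
    exponential-plus-offset decay fits, time-constant rescaling between
    phase-change and movement units), spatial-transfer predictions, and a
    synthetic-subject generator with known ground truth for validating the
    analysis pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    minpack.lm,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
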