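Package: cmpkin
Title: Kinetics of Casein Microparticle Size Changes Under Simulated
    Gastric Conditions
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Models and fits the size kinetics of spherical casein
    microparticles (CMPs) exposed to simulated gastric fluid: the
    acid-induced two-step shrinkage described by a Gaussian-outflow
    volume balance with an error-function closed form, the anomalous
    swelling that follows the isoelectric point, and the pepsin-induced
    exponential decay to a plateau. Provides the spherical-approximation
    geometry linking projected area and volume, a stock-and-flow system
    dynamics simulator with fixed-step Euler integration, constrained
    nonlinear least-squares and differential-evolution parameter
    estimation, a synthetic microscope-series generator with known
    ground truth, and a small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    minpack.lm,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
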