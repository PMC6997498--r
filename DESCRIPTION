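Package: audlearn
Title: Behavioral and Neural-Population Analysis of Auditory Perceptual Learning
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Analysis toolkit for go/no-go auditory perceptual-learning
    experiments in rodents. Computes signal-detection behavioral metrics
    (d-prime learning curves, psychometric decision boundaries, lick-based
    detection times), single-neuron tuning statistics (PSTHs, response
    windows, frequency-response areas, best frequency, selectivity, signal
    correlations), a generative SVD basis-function model of tuning-curve
    ensembles with Poisson trial noise, Poisson Fisher information and
    linear-decoder discriminability along the frequency axis, and
    sparseness/decorrelation analysis of responses to natural vocalizations.
    Includes a synthetic-data generator that emulates the statistical
    structure of cell-attached recordings from mouse auditory cortex so
    every analysis stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    e1071,
    jsonlite,
    minpack.lm
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
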