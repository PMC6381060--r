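Package: skewadapt
Title: Recurrent V1-MT Model of Motion Adaptation to Skew-Distorted Scenes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates motion-direction adaptation aftereffects (MAE) induced
    by geometrically skewed naturalistic image sequences. Provides a
    Reichardt-correlation motion front-end, a recurrent two-area (V1-MT)
    shunting circuit with short-term depressing synapses in the driving
    feedforward and modulatory feedback streams, a softmax decision readout,
    simulated psychophysical protocols at sub-second and minutes adaptation
    time-scales, and maximum-likelihood cumulative-Gaussian psychometric
    fitting with PSE-based aftereffect summaries. Includes generators for
    skew-distorted windowed image sequences, random-dot test stimuli and
    parametric direction-statistics surrogates.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
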