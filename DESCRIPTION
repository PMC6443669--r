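Package: salienceRL
Title: Cortical Recruitment as a Salience Parameter in Reinforcement Learning
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis tools for studying how the amount of
    cortical activity a stimulus recruits acts as its salience during
    reinforcement learning. Implements a multiplicative, asymmetric
    Rescorla-Wagner circuit model of Go/NoGo discrimination in both
    trial-by-trial stochastic and ergodic (mean-field) modes, learning-curve
    binning with sigmoid fits and delay/learning-phase extraction,
    calcium-imaging recruitment metrics (neuropil correction, dF/F0 baseline
    estimation, exponential-kernel deconvolution, population responses,
    responsive fractions, split-half similarity, linear decoding, grid-
    integrated firing rates), and synthetic-data generators with known ground
    truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    graphics,
    utils,
    minpack.lm,
    e1071,
    zoo,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
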