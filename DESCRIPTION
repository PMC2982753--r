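Package: orientpool
Title: Population Decoding of Spatial and Temporal Orientation Pooling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulates human global-orientation judgements as the read-out of a
    bank of orientation-tuned Poisson neurons. Skewed orientation distributions
    with distinct means, medians and modes are sampled into static or dynamic
    line textures, encoded as Poisson spike counts with Gaussian tuning
    curves, and decoded with vector-average, winner-takes-all and
    maximum-likelihood estimators. A simulated two-alternative forced-choice
    observer with method-of-constant-stimuli sampling, binomial logistic
    psychometric fitting and bootstrap confidence intervals recovers points of
    subjective equality, allowing the decoders' predictions to be compared
    with psychophysical results on orientation pooling across space and time.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    tools,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
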