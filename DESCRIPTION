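Package: tirsim
Title: Feedback-Based Temporal Control of Articulatory Gestures
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A fixed-step dynamical-systems simulator of articulatory timing in
    which gestural activation is gated by time-representing systems: autonomous
    aperiodic clocks, phase-coupled planning oscillators, and integrators of
    internal (predictive) or external (delayed sensory) feedback. Includes
    competitive selection of syllable-sized motor plans and word-sized concept
    systems, speech-rate control through attention-modulated integration rates
    and pace-modulated oscillator frequencies, a model zoo of three-gesture
    control topologies, and Monte-Carlo experiments on the covariance of
    successive inter-initiation intervals under global and local rate noise.
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
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
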