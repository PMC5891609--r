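Package: iatrace
Title: Interactive-Activation Simulation of Spoken Word Recognition
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A localist interactive-activation (TRACE-family) simulator of
    spoken word recognition with reduplicated feature, phoneme and word
    layers, lateral inhibition, and toggleable lexical-to-phoneme feedback.
    Provides Gaussian input-noise corruption, Luce-choice recognition
    scoring with threshold calibration, batch experiments over whole
    lexicons crossing noise level with feedback, item-level
    feedback-advantage analysis, gang/embedding competitor diagnostics,
    architecture complexity accounting, and a synthetic-lexicon generator
    with controlled cohort, embedding and gang structure.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    tibble,
    dplyr,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
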