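Package: neckereeg
Title: Single-Trial EEG Classification of Bistable Percepts with a
    Sample-Wise Multilayer Perceptron
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for classifying single-trial multichannel EEG into two
    perceptual-interpretation states (left- vs right-oriented Necker cube).
    Implements ocular-artifact removal by Gram-Schmidt orthogonalization
    against normalized EOG references, sample-wise multilayer-perceptron
    classification with a mean-squared-output decision statistic trained by
    Levenberg-Marquardt with multi-restart selection, within- and
    cross-subject evaluation, continuous Morlet-wavelet time-frequency
    contrasts, and event-related-potential difference traces.  Ships a
    seeded synthetic EEG generator (1/f background, occipital alpha rhythm
    with stimulus-locked desynchronization, class-dependent evoked and
    induced components, linearly mixed blink/saccade artifacts) so the full
    pipeline is testable without recordings, plus EDF input/output and a
    configuration-driven experiment runner.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    pracma,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr
Suggests:
    minpack.lm,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
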