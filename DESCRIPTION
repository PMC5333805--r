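Package: twitchva
Title: Voluntary Activation from Interpolated-Twitch Dynamometry
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for estimating voluntary activation of muscle
    with the interpolated twitch technique. Converts raw isometric joint-moment
    recordings with superimposed electrical stimulation into per-arm,
    per-posture voluntary-activation estimates: transducer calibration,
    zero-phase Butterworth filtering, windowed moment statistics, twitch
    amplitude extraction, linear extrapolation of twitch amplitude against
    voluntary moment to the full-activation moment, and heteroscedastic
    linear mixed-model group comparisons with Bonferroni post-hocs. Includes
    a synthetic-experiment generator with known ground truth so every stage
    can be validated by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    nlme,
    emmeans,
    jsonlite,
    graphics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
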