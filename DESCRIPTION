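Package: persifade
Title: Simulation and Analysis of Visible Persistence for Single-Transient
    Random-Dot Stimuli
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying visible persistence, the continued percept of
    a stimulus after its physical termination.  Generates random-dot matrices
    whose transition flips pixel polarity inside a disk- or annulus-shaped
    region (a single second-order transient), renders contrast-decay proxy
    stimuli driven by a calibrated three-stage linear-system impulse response,
    simulates the judgment-of-synchrony adjustment procedure with parametric
    synthetic observers, and runs the statistical pipeline: onset/offset
    synchrony estimates and visible-persistence durations, repeated-measures
    ANOVA with Greenhouse-Geisser correction, within-subject confidence
    intervals, drift-based subject screening, and the contour-length /
    fill-distance regression with cross-experiment prediction.
License: MIT
Encoding: UTF-8
Imports:
    png,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
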