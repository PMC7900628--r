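Package: contourgaze
Title: Contour-in-Noise Psychophysics: Stimulus Generation, Double-Pass
    Internal-Noise Estimation, and Gaze Point-Pattern Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for contour-integration experiments with Gabor elements
    embedded in orientation noise. Generates hexagonal-grid Gabor displays,
    balanced orientation-jitter noise, and blocked double-pass session
    designs; simulates a synthetic two-group observer cohort (responses,
    reaction times, gaze positions) with additive and stimulus-dependent
    internal noise; estimates the internal-to-external noise ratio from
    double-pass agreement/accuracy pairs via a bivariate-normal linear
    amplifier model and the fixed-point log-regression of percent correct on
    percent agreement; and analyses gaze positions as spatial point patterns
    (quadrat tests, inhomogeneous Poisson intensity models fitted by
    Berman-Turner quadrature, inhomogeneous K-function envelopes, variance
    ellipses, Bayesian-bootstrap group comparisons).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    png,
    yaml,
    optparse
Config/testthat/edition: 3
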