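Package: ssvepContext
Title: Frequency-Tagged ssVEP Analysis of Threat Generalization in Aversive Contexts
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: End-to-end analysis pipeline for steady-state visually evoked
    potential (ssVEP) frequency-tagging studies of conditioned threat
    generalization under aversive versus neutral contexts. Provides a
    synthetic-data generator emulating an 8-orientation x 2-context
    conditioning design (epoched dense-array EEG with 1/f background noise,
    pupil traces with blinks, US-expectancy rating tables, pseudo-randomized
    trial schedules), SCADS-style statistical artifact screening with
    spherical-spline sensor interpolation, current-source-density (surface
    Laplacian) transformation, cycle-aligned FFT power spectra with
    neighbour-bin signal-to-noise ratios at the fundamental (7.5 Hz) and
    second harmonic (15 Hz), repeated-measures ANOVA with Greenhouse-Geisser
    correction and noncentral effect-size confidence intervals, JZS
    Bayes-factor weight-model comparisons and topographies (sharpening,
    generalization, context), and a Monte-Carlo power simulation for
    correlated repeated measures.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    signal,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pracma,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
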