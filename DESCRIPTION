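Package: edaresonance
Title: Gesture Expressivity and Electrodermal Resonance in Conversational
    Storytelling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for studying whether the kinematic
    expressivity of co-speech gestures drives emotional (electrodermal)
    resonance between participants in conversational storytelling.
    Provides readers for time-aligned annotation tiers (ELAN EAF or a
    documented tabular dialect) and 4 Hz skin-conductance traces;
    derivation of the Gesture Expressivity Index (GEI) and its seven
    binary components together with positional, quotation and sentiment
    covariates; gesture-aligned electrodermal response windowing,
    specific-response classification (trough-to-peak amplitude above
    0.05 microsiemens) and cross-participant resonance detection;
    inter-rater agreement statistics (percent agreement and the
    Holley-Guilford G index); mixed-effects models for the gestural
    crescendo and expressivity-arousal questions with likelihood-ratio
    tests and Nakagawa conditional pseudo-R-squared; and a Random Forest
    stage with out-of-bag permutation importance, fit metrics and
    individual conditional expectation (ICE) curves. A synthetic
    multiparty conversation and electrodermal activity generator with
    ground truth supports end-to-end recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    lme4,
    Matrix,
    randomForest,
    jsonlite,
    xml2,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
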