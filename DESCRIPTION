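Package: p300aptitude
Title: Simulation and Prediction of P300 Brain-Computer Interface Aptitude
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools to simulate multichannel EEG for auditory oddball and
    visual/auditory P300 speller sessions with planted event-related
    potential components, preprocess recordings (zero-phase least-squares
    FIR band-pass, AMUSE blind source separation for ocular artifact
    removal, common average reference, epoching with baseline correction),
    classify target/non-target responses with stepwise linear discriminant
    analysis (SWLDA), evaluate speller performance (leave-one-run-out cross
    validation, accuracy versus stimulus repetitions, interpolated
    repetitions-to-criterion, Pierce and mutual-information transfer
    rates), detect N200/P300/late ERP components, and correlate oddball
    ERP features with speller aptitude via Spearman rank correlation maps.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    tools,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
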