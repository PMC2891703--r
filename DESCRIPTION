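Package: hifscreen
Title: Hit Calling for Plate-Based RNAi Reporter Screens of HIF-Dependent
    Transcription
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for multi-phase, plate-based RNAi reporter
    screens of hypoxia-inducible factor (HIF) dependent transcription in
    Drosophila cells: plate-wise Z-score normalisation of luminescence,
    threshold hit calling with replicate rules, sequential exclusion-list
    filtering, firefly/Renilla dual-reporter percent-inhibition
    classification with at-least-one-amplicon logic, and the downstream
    quantification assays (delta-delta-Ct relative qPCR expression and
    kinetic beta-galactosidase activity). Includes a synthetic-screen
    generator with log-normal well noise, multiplicative plate effects,
    control wells, and planted knockdown effects, so every stage of the
    pipeline can be tested against a known ground truth without external
    screen data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
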