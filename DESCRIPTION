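Package: cvepr
Title: Decoding and Simulation Tools for c-VEP Brain-Computer Interface Spellers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for code-modulated visual evoked potential (c-VEP)
    brain-computer interface spellers: circular-shift m-sequence codebooks,
    template generation and spatial-filter ensembles via canonical
    correlation analysis (CCA), individualized Butterworth filter-bank
    weighting, synchronous and asynchronous threshold-based dynamic-window
    classification, speller state machines (4-target multi-step and
    32-target single-step layouts with bigram word suggestions), performance
    metrics (accuracy, information transfer rate, output characters per
    minute), and a seeded synthetic-EEG generator plus offline
    cross-validation harness so every stage runs without recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
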