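Package: vspredictor
Title: Episode Mining and State Prediction for Vital-Sign Streams
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discretizes timestamped vital-sign measurements (blood pressure,
    pulse oximetry, heart rate) into clinical state events, mines frequent
    serial episodes from the resulting complex event sequence by counting
    minimal occurrences, maintains the episode table incrementally under a
    sliding window, derives confidence-ranked episode rules, predicts the
    upcoming vital-sign state of a monitored subject, and maps predictions to
    care guidelines. Includes a synthetic stream generator with planted
    temporal dependencies for end-to-end validation, plus command-line entry
    points for offline rule building and online streaming prediction.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    optparse,
    yaml,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
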