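Package: damtel
Title: Acoustic Telemetry Filtering, 3-D Localization and Dam Passage Route
    Assignment
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A processing pipeline for dam-scale acoustic telemetry of
    juvenile fish carrying JSATS-style coded transmitters. Implements the
    31-bit tag-code layout with 8-bit CRC validation and mimic-code
    analysis, the false-positive detection filter cascade (multipath,
    single-detection, ping-rate-interval, mimic and chronology filters),
    time-difference-of-arrival hyperbolic 3-D localization with a damped
    Gauss-Newton solver, trajectory outlier cleaning, dam passage-route
    assignment from 3-D tracks and last-detection pier averaging, and
    GPS-referenced accuracy validation. A seeded simulator generates
    synthetic hydrophone arrays, fish tracks, transmissions, decodes and
    survey-vessel reference data so every stage is testable without field
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    minpack.lm,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
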