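Package: flightcheck
Title: Inertial-Sensor Detection of Illegal Race-Walking Steps
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Detects loss-of-ground-contact (flight) in race walking from a
    single sacrum-mounted tri-axial accelerometer. Implements zero-phase
    low-pass filtering, vertical-acceleration step-cycle minima, heel-strike
    detection from the anteroposterior channel, and a per-step offset test
    against a 0.03 s flight threshold; computes the high-speed-camera
    reference measurement from frame counts; and validates sensor against
    camera with limits-of-agreement statistics (typical error of the
    estimate, mean bias, Pearson correlation), operator-reliability analysis
    (typical error, intraclass correlation) and a confusion/accuracy summary.
    Includes a synthetic race-walk gait-signal simulator with known event
    times and paired quantised camera annotations, so the whole pipeline is
    testable without recorded data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    pracma,
    jsonlite,
    yaml,
    ggplot2,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
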