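Package: rtfusion
Title: Simulation and Analysis of Smartphone Audio-Tactile Reaction-Time
    Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for validating smartphone-based audio-tactile reaction-time
    (RT) paradigms without hardware. Simulates accelerometer traces, frame-
    quantized touchscreen events and timing-validation bench sessions from
    declarative device profiles; implements an EWMA-envelope onset detector
    and a touchscreen/accelerometer timestamp-fusion rule that improves RT
    resolution beyond the touchscreen refresh period; computes stimulus-timing
    accuracy and precision statistics and device-suitability verdicts;
    generates peripersonal-space session schedules with looming and fixed
    sound conditions and catch trials; simulates lognormal participant cohorts
    with tactile-expectancy and looming-facilitation effects; and runs the
    full RT analysis pipeline (exclusion, filtering, log-transformed condition
    means, per-delay contrasts, two-way within-subject ANOVA).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
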