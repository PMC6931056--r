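Package: gaitfeedback
Title: Heel-Strike Detection and Real-Time Gait Feedback from Ankle Gyroscope Signals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects heel-strike events in sagittal-plane angular velocity
    recorded by an ankle-worn gyroscope, classifies each step as "good" when
    the post-heel-strike deceleration peak crosses a configurable threshold,
    emulates the real-time per-step auditory feedback loop of wearable gait
    trainers, and computes session-level gait quality metrics (proportion of
    good steps, cadence, walking time, angular-velocity mean/SD/CV, walking
    bouts) together with pre/post clinically-important-change reports. A
    synthetic gait simulator with known ground truth makes every stage
    testable without real recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    signal,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
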