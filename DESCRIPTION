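Package: entrainr
Title: Accelerometer Tremor Analysis and Cued Entrainment Therapy Sessions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Offline engine for entrainment-based retraining of functional
    tremor. Estimates the dominant tremor frequency from 3-axis wrist
    accelerometer recordings by tapered FFT, drives a seven-day cued-session
    protocol (auditory cue at 2/3 then 1/3 of the baseline tremor frequency,
    with treatment-frequency clamps), tracks the voluntary movement frequency
    in sliding windows, maps it onto a bounded biofeedback gauge centred on
    the goal frequency, and persists time-stamped session logs with
    duration-weighted completion metrics. Includes a simulator of tremor and
    of cue-following subjects so every stage is testable without hardware,
    and a command-line interface for reproducible runs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    signal,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
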