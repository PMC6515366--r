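Package: affectsense
Title: Emotion Recognition from Wearable Biosignals and Emotion-Aware
    Activity Recommendation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates multi-channel physiological recordings (ECG, PPG,
    electrodermal activity) as acquired by a low-cost wearable sensing
    chain (voltage divider, amplifier, mains contamination, motion
    artifact, 12-bit ADC), removes 50 Hz powerline interference with a
    zero-phase Butterworth band-stop filter, extracts the six classic
    per-channel affective-computing statistics (mean, standard deviation,
    and mean absolute first/second differences, raw and z-normalised),
    trains a fully connected 18-input/7-emotion neural network classifier,
    and recommends physical activities matched to a user's health profile
    and current emotional state, with preference learning from
    accept/deny feedback and caregiver notifications.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    signal,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
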