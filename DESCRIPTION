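Package: pulsecam
Title: Cam-Based Radial Pulse Simulator Design and Waveform Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for designing and validating cam-follower radial pulse
    simulators. Extracts a representative radial pressure waveform from an
    ensemble of tonometry pulses by an augmentation-index-penalized Fourier
    minimization, converts the waveform into a closed polar cam profile (one
    pulse period per revolution), plays the cam back as a pressure waveform at
    a commanded heart rate and pulse pressure, and quantifies fidelity via the
    radial augmentation index and discrete-Fourier-transform phase-angle
    delay. Includes a seed-deterministic synthetic pulse generator so the
    whole pipeline is testable without clinical recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    optparse,
    signal,
    stats,
    utils
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
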