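Package: empain
Title: EMG-Driven Fuzzy Pain Estimation and Stimulation Control for
    Robot-Assisted Rehabilitation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulation and analysis toolkit for an EMG-based pain-aware
    controller used in robot-assisted elbow/forearm rehabilitation.
    Generates synthetic surface-EMG, motor-current and range-of-motion
    traces; conditions raw EMG with Butterworth band-pass and 50 Hz notch
    filters; extracts four time-domain features (RMS, simple square
    integral, v-order, log detector) per analysis window; estimates
    muscle contraction and pain level with a two-block Mamdani fuzzy
    inference cascade (Gaussian membership functions, center-of-area
    defuzzification); and runs closed-loop rehabilitation sessions that
    select electrical-stimulation modes (pain relief, massage, relax)
    from the estimated pain.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    signal,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
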