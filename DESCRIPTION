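Package: vasoppg
Title: Vasoconstriction Detection from Chest Photoplethysmography
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Signal-processing pipeline for detecting systemic
    vasoconstriction events in dual-channel (red and infrared)
    photoplethysmogram recordings from a chest-worn sensor sampling at
    50 Hz. Provides biased autocorrelation and a beat-lag periodicity
    score for signal-quality assessment, Kaiser-window FIR band-pass
    filtering, Hilbert analytic-envelope perfusion tracking with a 60 s
    running-average baseline, a percent-vasoconstriction statistic with
    small/medium/large event binning, device-agreement statistics
    (confusion agreement, Bland-Altman limits, correlation r-squared,
    two-sample Z-test), a synthetic dual-channel PPG generator with
    programmable constriction events for validation, and CSV recording
    input/output.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    jsonlite,
    yaml
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0),
    signal,
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
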