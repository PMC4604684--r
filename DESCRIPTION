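Package: pulsewave
Title: Arterial Pulse-Waveform Phenotyping of Hemodynamic Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Beat-by-beat analysis of continuous arterial blood-pressure
    recordings as used in murine cardiovascular phenotyping: segmentation of
    pressure traces into beats, detection of the systolic peak, end-diastole,
    dicrotic notch and anacrotic notch (third zero crossing of the fourth
    derivative), derived pressure metrics (pulse pressure, mean arterial
    pressure, augmentation pressure and index, diastolic decay time constant),
    artifact-beat gating, four-parameter logistic vasopressor dose-response
    fitting (ED50, Emax), radial morphometry of aortic-ring cross sections
    (intima-media thickness, elastic laminae counts), and the group statistics
    used with such data (trimmed means, Student t-tests, the ratio t-test).
    Includes closed-form synthetic-data generators with analytic ground truth
    for all waveform landmarks, so every stage is testable without recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    signal,
    minpack.lm,
    jsonlite,
    yaml,
    png,
    tiff,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
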