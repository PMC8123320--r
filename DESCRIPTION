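Package: cardioresp
Title: Cardio-Respiratory Rate Estimation from Wearable Strain and
    Inertial Sensors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Estimation of respiratory rate from conductive-textile chest
    strain channels and of heart rate from seismo- and gyrocardiographic
    IMU channels via Hilbert-envelope demodulation. Implements zero-phase
    Butterworth conditioning, Welch power-spectral-density rate
    estimation, breath-by-breath inspiratory-peak detection, windowed
    short-time heart-rate tracking, and method-agreement statistics
    (mean absolute error, Bland-Altman limits of agreement). Includes a
    synthetic chest-worn-sensor trial generator with known ground truth
    (calibrated strain-to-voltage sensor model, amplitude-modulated
    heartbeat carrier, scenario-dependent motion artifact) so the whole
    pipeline is exercisable without human recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    jsonlite,
    signal,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
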