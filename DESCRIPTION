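Package: fdmdnirs
Title: Frequency-Domain Multi-Distance NIRS Analysis of TMS-Evoked Hemodynamics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of frequency-domain multi-distance (FDMD)
    near-infrared spectroscopy recordings of cortical hemodynamic responses to
    single-pulse transcranial magnetic stimulation (spTMS) before and after
    theta-burst stimulation (cTBS/iTBS). Provides a forward photon-density-wave
    simulator with stimulation-session scheduling and physiological noise, the
    multi-distance slope inversion to absorption and reduced scattering
    coefficients with R-squared quality gating, two-wavelength conversion to
    oxy-/deoxyhemoglobin and total hemoglobin (blood volume), Hanning
    windowed-sinc bandpass filtering, event segmentation with baseline
    normalization and discard rules, and event-level statistics (Welch tests
    and random-intercept linear mixed models over the condition contrast
    matrix).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    graphics,
    nlme,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
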