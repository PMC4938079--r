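Package: pulsewave
Title: Subject-Specific One-Dimensional Modelling of Aortic Pulse Wave
    Haemodynamics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Nonlinear one-dimensional (1D) blood flow simulation on a
    subject-specific upper-aorta network coupled to three-element Windkessel
    outflow models, together with the complete workflow that personalises
    every material and boundary-condition parameter from non-invasive flow,
    luminal area and tonometry pressure waveforms. Includes pulse wave
    velocity estimation by the foot-to-foot and QA-loop methods, calibration
    of peripheral resistances and compliances from a lumped analysis of the
    diastolic pressure decay, data-reconciliation procedures for
    inconsistent heart rates, geometry and mean flows, and a deterministic
    synthetic-data generator that emulates gated PC-MRI, cine SSFP and
    applanation tonometry measurements.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    minpack.lm,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
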