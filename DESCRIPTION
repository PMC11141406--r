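Package: rsakit
Title: Radiostereometric Analysis of Implant Migration
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A toolkit for marker-based radiostereometric analysis (RSA) and
    CT-based migration measurement (CT-RSA) of joint replacements. Covers
    calibration of stereo roentgen projections from a calibration cage,
    triangulation of tantalum marker positions, rigid-body registration with
    mean-error and condition-number quality metrics, standardized migration
    computation (signed translations and body-fixed XYZ Euler rotations,
    total translation/rotation, point motion and maximum total point motion),
    double-examination precision analysis, phantom accuracy experiments,
    Bland-Altman method comparison, sample-size and screening-risk
    calculations, and checklist-compliant study reporting. Includes a
    synthetic phantom and longitudinal-study generator for end-to-end
    validation of the measurement pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    minpack.lm,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
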