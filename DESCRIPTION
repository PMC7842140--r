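Package: dvrmodel
Title: Dose-Volume Response Modelling of Radiation-Induced Brain Lesion Growth
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Fits and simulates a dose-volume response model for
    radiation-induced blood-brain-barrier damage in mouse brain, observed as
    contrast-enhancing (CE) lesions on T1-weighted MRI. The model couples a
    logarithmic dose dependence of lesion onset time with a power-law growth
    of log lesion volume over follow-up time. The package provides closed-form
    onset regression, global nonlinear volume fitting with one-parameter
    cross-strain transfer, a seeded virtual-cohort simulator emulating a
    two-strain preclinical MRI follow-up study (biweekly scans, detection and
    sacrifice thresholds, censoring at the follow-up horizon), Kaplan-Meier
    and log-rank survival analysis, and CSV/JSON interfaces with a small
    command-line driver.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    minpack.lm,
    survival,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
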