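Package: bilatopo
Title: Bilateral Differential Corneal Topography for Keratoconus Screening
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Computes bilateral differential corneal topography from paired
    right/left-eye topographic grids: the fellow eye's maps are mirror-flipped
    about the vertical meridian, subtracted cellwise, and the absolute
    difference is summarised inside a central 1.5-mm-radius zone into twelve
    characteristic parameters (max, mean and population standard deviation of
    the front-keratometry, front-elevation, back-elevation and pachymetry
    differentials). Includes Mann-Whitney group testing, ROC analysis with
    Youden cutoff selection and DeLong confidence intervals, a classifier
    shipping clinically validated thresholds, and a conicoid-based paired
    cornea simulator for generating enantiomorphic and keratoconic test
    cohorts.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
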