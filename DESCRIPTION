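Package: thermocov
Title: Coverage Analysis of Fractional Laser Treatment from Skin Thermograms
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Automatic analysis of infrared thermograms of skin acquired
    during fractional laser treatment. Locates the treated skin region,
    estimates the common rotation angle of the pulse grid from a Radon
    transform of Canny edges, segments individual laser pulse footprints
    with marker-controlled watershed, approximates each footprint by a
    rotated square, and quantifies treatment correctness as two coverage
    errors: the percentage of the treated region receiving no dose and the
    percentage receiving an overlapping (double) dose.  Includes a
    synthetic thermogram generator with pixel-exact ground truth so every
    stage of the pipeline can be validated without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    data.table,
    EBImage,
    jsonlite,
    Rcpp,
    stats,
    tiff,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
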