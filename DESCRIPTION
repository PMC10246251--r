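Package: hemovol
Title: Hemorrhage Volumetry and Expansion Detection on Non-Contrast Head CT
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Automated intracerebral hemorrhage (ICH) volumetry on
    non-contrast head CT: brain-median-relative Hounsfield-unit
    thresholding, anatomical false-positive rejection of dural and
    falcine hyperdensities, 3D connected-component volumetry, serial-scan
    hematoma-expansion classification under the conjunction rule
    (>= 6 cc absolute and >= 33 percent relative growth), and
    diagnostic-accuracy evaluation with exact binomial and log-method
    confidence intervals. Includes a synthetic head-phantom generator
    with known ground-truth lesion volumes so the whole pipeline can be
    exercised without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    RNifti,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
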