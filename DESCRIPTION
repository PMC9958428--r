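Package: ctprep
Title: Batch Pre-Processing of CT DICOM Studies for Quantitative Osteology
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Prepares raw computed-tomography studies for large-scale morphometric
    and machine-learning work. Sorts mixed DICOM dumps into per-series folders,
    removes non-patient structures (scanner couch, tubing) by Hounsfield-unit
    thresholding and largest-component patient masking with in-place overwrite,
    and emits three output classes: windowed 2-D images (PNG/JPEG), one NIfTI
    volume per series, and STL bone-surface meshes extracted by marching cubes.
    Includes a synthetic CT phantom generator with analytic ground truth so the
    whole pipeline is testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    EBImage,
    RNifti,
    png,
    jpeg,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
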