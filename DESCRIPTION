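Package: hipplan
Title: Landmark-Based Pre-Surgical Planning Geometry for Revision Hip Arthroplasty
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Geometric toolkit for CT-based pre-surgical planning of revision
    hip arthroplasty. Builds the three anatomical reference planes (sagittal,
    axial, coronal) and an orthonormal pelvic frame from six bony landmarks,
    fits a least-squares sphere to the intact femoral head, mirrors its center
    of rotation across the sagittal plane to plan the revision-side cup
    position, parameterizes acetabular cup poses by radiographic inclination
    and anteversion, generates hemispherical cup shell meshes and screw
    trajectories against bone surface meshes, and evaluates planned-versus-
    achieved agreement (paired t, Pearson correlation, Kolmogorov-Smirnov
    normality, percent-difference accuracy tables). Reads and writes 3D Slicer
    markups (FCSV and JSON), binary and ASCII STL, and CSV measurement tables,
    and ships a synthetic-pelvis generator with configurable superior-medial
    ("up and in") and superior-lateral ("up and out") acetabular defects so the
    whole pipeline is testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    optparse,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
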