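Package: hermiteflow
Title: Steered Hermite Transform Optical Flow for Volumetric Image Sequences
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Dense 2D and 3D+t motion estimation with a differential,
    multiresolution optical-flow method built on the steered Hermite
    transform, a bio-inspired local image decomposition onto Gaussian
    derivative filters. Provides the discrete Hermite analysis and
    synthesis filter banks, per-voxel orientation estimation and
    coefficient steering, a coarse-to-fine warping Horn-Schunck-family
    solver augmented with steered-coefficient constancy constraints,
    interpolation-error validation metrics, synthetic motion phantoms
    with analytic ground truth (including a beating ellipsoidal-shell
    ventricle model), and readers and writers for NIfTI, TIFF,
    Middlebury .flo and legacy VTK vector fields.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    tiff,
    png,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    yaml,
    optparse
Config/testthat/edition: 3
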