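Package: ChondroCT
Title: Cartilage-Compensated Reconstruction of Proximal Radius Models from CT
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Reconstructs the cartilage-bearing articular surface of the radial
    head from bone-only computed tomography. Plain CT segments subchondral bone
    and misses the 0-3.5 mm articular cartilage layer; this package implements a
    cartilage-reproducing image reconstruction method that translates the
    articular subchondral contour halfway across the joint gap at the proximal
    radioulnar and radiocapitellar joints. It also provides Hounsfield-threshold
    bone segmentation, seed-based bone labelling, watertight isosurface meshing,
    rigid surface registration with RMS deviation colormaps, the five standard
    radial-head morphometric parameters (coronal and sagittal diameter, medial
    and lateral rim thickness, articular disc depth), Friedman rank tests with
    Bonferroni-adjusted pairwise comparisons, and a synthetic elbow phantom
    generator that supplies an analytic bone-plus-cartilage ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    RNifti,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
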