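Package: angiorecon
Title: Patient-Specific 3D Coronary Vessel Reconstruction from Biplane X-Ray Angiograms
Version: 0.1.0
Authors@R: person("angiorecon", "developers", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Semi-automatic reconstruction of three-dimensional coronary
    vessel surface models from two monoplane X-ray angiogram projections.
    Provides multiscale Hessian-eigenvalue vessel enhancement, hysteresis
    thresholding, skeletonization with bifurcation/end-point detection,
    sub-pixel centreline extraction, dynamic-programming delineation of the
    two vessel wall curves on normals to the centreline, epipolar two-view
    3D centreline reconstruction with iterative foreshortening correction,
    per-point radius estimation, Frenet-frame tube meshing with STL/OBJ
    export, and validation tools (Hausdorff distance, maximum-likelihood
    multi-annotator label fusion). A built-in vascular phantom generator
    renders synthetic projection pairs with full ground truth so the whole
    pipeline is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    png,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
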