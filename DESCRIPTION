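Package: coroseg
Title: Coronary CTA Vessel Wall and Plaque Segmentation with Level Sets
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Automatic three-dimensional segmentation of the coronary artery
    lumen and outer vessel wall from contrast-enhanced computed tomography
    angiography. Robust initial contours are built by intersecting
    region-growing results on the Hounsfield image and on a multiscale
    Hessian (Frangi) vesselness image; the inner and outer walls are then
    refined by two edge-based geodesic level sets evolving in opposite
    directions, the outer one started from a 5.5 mm fat-restricted geodesic
    dilation of the lumen. Downstream tools extract the zero-level surface
    mesh, a medial-axis centerline with Frenet-Serret / parallel-transport
    frames, a curved multiplanar reformation (vessel straightening) with
    radial longitudinal sections and wall-thickness profiles, and pooled
    volumetric agreement metrics (DICE, volume MSE, relative volume error,
    precision, sensitivity, Bland-Altman). A synthetic vascular phantom
    generator with analytic ground truth supports validation end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    RNifti,
    Rcpp,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
SystemRequirements: C++17
Config/testthat/edition: 3
RoxygenNote: 7.3.3
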