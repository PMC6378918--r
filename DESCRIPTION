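Package: ecgi
Title: Electrocardiographic Imaging of Ischemic Lesions on a Synthetic Heart-Torso Phantom
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and inverse-reconstruction pipeline for ECG imaging
    (ECGI) of ventricular ischemia. Builds synthetic heart-torso phantoms,
    simulates epicardial action-potential fields with a two-zone transmural
    ischemic lesion, computes body-surface potentials with a boundary element
    method transfer matrix, samples limited electrode grids, interpolates the
    body-surface map by harmonic (Laplacian) extension, solves the ill-posed
    inverse problem with zero-, first- and second-order Tikhonov
    regularisation and L-curve corner selection of the regularisation
    parameter, and scores lesion detection (correctly-ischemic /
    incorrectly-healthy / incorrectly-ischemic areas) and reconstruction
    error (relative difference measure star) across electrode count, lesion
    location and size, noise level and detection-threshold sensitivity.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    igraph,
    stats,
    utils,
    graphics,
    tools
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
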