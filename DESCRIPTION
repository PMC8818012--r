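Package: epifield
Title: Epileptor Neural-Field Simulation of Seizure Spread on Cortical
    Surfaces with SEEG Forward Modeling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates epileptic seizure propagation with the Epileptor
    neural-field model on triangulated cortical surface patches, projects
    the simulated source activity to stereo-EEG (SEEG) depth-electrode
    sensors through a dipole gain matrix, and quantifies the resulting
    seizure-onset patterns.  Includes mesh utilities (refinement, vertex
    areas and normals, geodesic distances, patch extraction), generators
    for surrogate cortical surfaces (flat, sinusoidal, and seeded gyral
    sheets) with depth electrodes, bifurcation scans of the single-node
    model, envelope-based onset detection, seizure-spread and fast-wave
    velocity estimators, coupling-strength calibration, and an
    identifiability experiment comparing candidate surfaces against a
    reference recording.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    Matrix,
    igraph,
    signal,
    jsonlite,
    tools,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
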