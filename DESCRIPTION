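Package: pseudotax
Title: Pseudopod-Centred Simulation and Analysis of Eukaryotic Chemotaxis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates amoeboid cell migration and chemotaxis with a
    pseudopod-centred feedback model. A Meinhardt-type activator /
    two-inhibitor reaction-diffusion system is solved on the closed, moving
    cell perimeter with piecewise-linear surface finite elements and
    semi-implicit time stepping, while the perimeter itself is advanced by a
    level-set method with an activator-proportional protrusion law and
    curvature-based retraction. Chemoattractant fields (linear gradients,
    point sources, uniform steps with receptor adaptation, scheduled
    reorientation) drive the system through local fractional receptor
    occupancy with multiplicative noise. An analysis layer detects
    pseudopods as activator peaks, tracks their lifetimes and bifurcations,
    classifies fates, and computes split-angle statistics, chemotaxis
    indices, and kymographs.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    Rcpp,
    stats,
    grDevices,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
LinkingTo: Rcpp
Config/testthat/edition: 3
RoxygenNote: 7.3.3
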