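Package: pitflow
Title: Virtual Pit-Membrane Microstructure, Microflow and Mechanics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Builds virtual three-dimensional xylem pit-membrane
    microstructures by random sequential deposition of rigid cellulose
    microfibrils, voxelizes them, extracts pore/constriction networks via
    an exact Euclidean distance transform and watershed segmentation,
    solves steady creeping (Stokes) flow through the fibrous membrane on a
    staggered voxel grid with Darcy upscaling and per-pore flux
    attribution, and estimates membrane mechanics with the Cox shear-lag
    formula and a bonded beam-network tension simulation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Matrix,
    igraph,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
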