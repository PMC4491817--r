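Package: tomopore
Title: Subtomogram Averaging and Hierarchical C8 Analysis of Nuclear Pore
    Complexes from Cryo-Electron Tomograms
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for reconstructing an averaged, locally
    resolution-annotated density map of the nuclear pore complex (NPC)
    from cryo-electron tomography data.  Covers the full computational
    route: simulation of tilt series from synthetic pore phantoms,
    strip-based CTF estimation and phase-flip correction, weighted
    backprojection, missing-wedge constrained cross-correlation
    alignment and averaging of subtomograms, spheroid-based orientation
    verification, hierarchical C8 protomer and subprotomer averaging
    with eightfold model assembly, grid-based local resolution and
    cross-resolution mapping, and rigid-body docking of component
    densities with restraint-distance scoring.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
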