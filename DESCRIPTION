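Package: hotspotr
Title: Prediction of Hot Spot Residues at Protein-Protein Interfaces
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Identifies energetic hot spots among protein-protein interface
    residues from complex structures. Computes sequence, structure, solvent
    exposure and energy descriptors for interface residues, expands them over
    Euclidean and Voronoi (Delaunay) structural neighborhoods with
    burial-fraction weighting, selects an optimal feature subset with a
    two-step mRMR plus sequential-forward-selection procedure under a
    cross-validated composite criterion, and classifies residues with a
    gradient-boosted tree ensemble. Includes a Shrake-Rupley solvent
    accessible surface area implementation, a 3-D Delaunay tessellation,
    readers for PSI-BLAST PSSM, DSSP, disorder and hydrogen-bond files, and
    generators for fully synthetic test fixtures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    Biostrings
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
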