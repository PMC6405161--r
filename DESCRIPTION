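Package: epilesion
Title: Seizure Propagation and Targeted Virtual Disconnection on Structural Connectomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Patient-specific modelling of epileptic seizure propagation on
    weighted structural connectomes. Simulates a network of permittivity-coupled
    two-dimensional Epileptor neural mass models, predicts the propagation zone
    by linear stability analysis of the network fixed point (Jacobian
    eigenvalues and the leading eigenvector), and computes minimal targeted
    disconnection plans, benchmarked against full, random, and strongest-link
    lesioning strategies. Includes a seeded synthetic-connectome generator with
    planted ground-truth propagation scenarios, nodal graph metrics, a
    systematic epileptogenic-zone sweep, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    deSolve,
    igraph,
    signal,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
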