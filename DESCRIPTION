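Package: elbow4d
Title: Four-Dimensional Elbow Simulation for Debridement Arthroplasty Planning
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for four-dimensional (3D + time) simulation of elbow
    flexion-extension from surface models of the distal humerus and forearm.
    Fits the flexion-extension hinge axis with the two-rings landmark method
    (circles through points plotted on the trochlea and capitellum, axis
    through the two circle centers), rotates the forearm rigidly about that
    axis, quantifies and localizes bony impingement as voxelized overlap
    volumes at any flexion angle, and estimates the impingement-free arc.
    Includes a parametric hinge-joint phantom generator with analytically
    known axis and osteophyte contact angles for validation, plus the
    reliability (one-way and two-way random intraclass correlation) and
    cohort statistics used to evaluate such simulations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    optparse,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
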