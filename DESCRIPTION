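Package: dgforest
Title: Context-Driven Synthesis of the Dentate Gyrus Granule Cell Dendritic Forest
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Generates complete populations of rat dentate gyrus granule cell
    dendritic morphologies inside a parametric model of the granule cell and
    molecular layers. A layered torus-derived volume is calibrated to the
    measured layer volumes and molecular-layer width; somata are packed on a
    hexagonal grid inside the granule cell layer; per-cell target points are
    sampled within anatomically oriented elliptical cones and connected by a
    greedy optimal-wiring rule balancing total cable length against somatic
    path length. Includes single-cell morphometrics (Sholl profiles,
    contraction, partition asymmetry, laminar distributions), population
    summaries, voxel-based occupancy and cable-density analyses, simulated
    axon complexity estimates, and SWC import/export.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    igraph,
    jsonlite,
    optparse,
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
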