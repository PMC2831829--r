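Package: apoptowave
Title: Reaction-Diffusion Modelling of Spatially Coordinated Apoptosis Execution
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulates the intrinsic apoptosis execution network (apoptosome,
    caspases-9/-3/-7, XIAP, Smac) as a one-dimensional reaction-diffusion
    system in a 30 micron model cell. Mitochondrial outer membrane
    permeabilisation (MOMP) is represented as a travelling wave of onset
    times driving saturating inputs for apoptosome formation and Smac
    release; all cytosolic proteins diffuse with Stokes-Einstein
    diffusivities scaled from a 27 kDa GFP reference. The package provides
    the mass-action network with perturbation variants (feedback knockouts,
    accelerated kinetics, apoptosome immobilisation, diffusivity scaling),
    a stiff method-of-lines solver, end-to-end anisotropy metrics
    (threshold crossing delays between the cell ends), a slab-versus-sphere
    dimensionality check, and a deterministic scenario runner with
    kymograph-style figures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    Rcpp,
    ggplot2,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
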