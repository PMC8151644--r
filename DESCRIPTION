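Package: tmesim
Title: Lattice Metropolis Monte Carlo Simulation of Bioprinted Tumor
    Microenvironment Constructs
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Simulates the post-printing evolution of bioprinted tumor
    microenvironment constructs on a 3D cubic lattice. Cancer and
    peritumoral cells embedded in hydrogel rearrange by Metropolis Monte
    Carlo trial moves driven by differential adhesion (works of cohesion
    and adhesion, derived interfacial tensions) and proliferate
    stochastically when in contact with hydrogel or culture medium.
    Includes rasterizers for toroidal and triple-layered construct
    geometries, random cell seeding at a prescribed volume fraction,
    morphometric descriptors (infiltration, wrapping, escape, cluster
    statistics), bundled parameter presets, trajectory tidiers and plots,
    XYZ/site-list/CSV export, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    igraph,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
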