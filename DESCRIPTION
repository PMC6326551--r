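Package: npflip
Title: Iterative Ligand Flipping and Insertion Energetics of Amphiphilic
    Nanoparticles in Lipid Bilayers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing the insertion of amphiphilic
    monolayer-protected gold nanoparticles into phospholipid bilayers by
    iterative flipping of charged ligands.  Builds mixed-monolayer
    nanoparticle and bead-bilayer geometries, generates synthetic
    nanoparticle-bilayer configurations with controlled ligand
    distributions, runs the biased ligand flip-flop workflow as a state
    machine, computes solvent-accessible surface areas by Shrake-Rupley
    sphere quadrature with hydrophobic free-energy scoring (gamma times
    the change in SASA), provides pair-distance statistics (radial
    distribution functions, contact counts, coordination numbers,
    cylindrical density maps, block-averaging errors), and assembles the
    six-state insertion free-energy landscape from its component
    estimates.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    broom,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
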