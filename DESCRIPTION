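Package: shellpockets
Title: Pocket Detection and Monolayer Statistics for Ligand-Shell-Protected Nanoparticles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Detects and characterizes transient binding pockets in the
    self-assembled ligand monolayer of coated nanoparticles from molecular
    dynamics snapshots.  Pockets are extracted on a voxel grid as the
    volumetric difference between two solvent-excluded surfaces computed with
    a water-sized and a larger spherical probe, then volume-filtered,
    geolocalized relative to the metal core, and fingerprinted by the ligand
    fragments (inner / central / outer blocks) that form their walls.
    Includes per-frame monolayer statistics (pocket counts, volume and depth
    classes, dihedral conformer fractions, hydrogen-bond fractions), analyte
    occupancy classification, free-energy bookkeeping from binding-constant
    ratios, seeded synthetic fixtures with known cavity structure, and an
    independent brute-force surface oracle for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tibble,
    dplyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    igraph,
    tools,
    withr,
    bio3d,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
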