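Package: nucleoflex
Title: Nucleosome Mechanics from Molecular Dynamics Fluctuations and AFM
    Nanoindentation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates the absolute Young's modulus of nucleosome-like
    particles from molecular dynamics trajectories by fitting a minimal
    elastic cylinder to windowed structural fluctuations and applying the
    equipartition theorem, and provides the in vitro counterpart: Hertz
    spherical-indenter fitting of AFM nanoindentation force curves and
    particle morphometrics (height, diameter, volume, roundness, cluster
    counting) on AFM height images. Also includes DNA gyre gaping/sliding
    geometry from labelled phosphate triads, PCA free-energy landscapes,
    per-residue RMSF profiles, and seeded synthetic-data generators with
    known ground truth for validating every estimator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    bio3d,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    optparse,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    igraph,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
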