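Package: solvtess
Title: Statistical Geometry of Binary Solvent Mixtures by Periodic
    Delaunay Tessellation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analyses the large-scale structure of simulated binary
    water-cosolvent mixtures by statistical geometry. Heavy-atom
    configurations (GRO, PDB or XYZ frames, or built-in synthetic
    generators) are partitioned by a periodic-boundary-aware Delaunay
    tessellation; each tetrahedron is classified by its water/cosolvent
    vertex composition (W4, W3S, W2S2, WS3, S4), class abundances are
    compared against a binomial random-mixing null through a log-odds
    statistic, and tetrahedral distortion is quantified by the
    tetrahedrality order parameter. Detects microheterogeneity
    (self-association of water and cosolvent) in mixtures such as
    water-acetonitrile and water-DMSO.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    withr,
    ggplot2
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    bio3d,
    optparse
Config/testthat/edition: 3
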