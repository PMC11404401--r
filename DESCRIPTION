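Package: polypotts
Title: Cellular Potts Model Simulations on Arbitrary Periodic Polygonal Lattices
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A generalized cellular Potts (Glazier-Graner-Hogeweg) model for
    confluent cell monolayers that runs on any periodic polygonal lattice:
    square, hexagonal, or disordered Voronoi lattices derived from a simulated
    fluid configuration. The surface-energy term is weighted by shared edge
    lengths so that the same Metropolis Monte-Carlo dynamics applies to regular
    and irregular substrates alike. Includes a periodic Voronoi tessellation
    engine, a spectral isotropy check for generated lattices, dynamic
    observables (center-of-mass trajectories, mean-squared displacement,
    diffusion exponent and coefficient, hexatic bond-orientational order),
    Voronoi-based cell-shape metrics (isoperimetric quotient, generalized edge
    number, Hu-moment circularity), and estimators that localize the
    fluid-solid transition of monodisperse confluent cells from surface-tension
    scans.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
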