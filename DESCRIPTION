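Package: polymc
Title: Coarse-Grained Chemical-Events Monte Carlo Simulation of
    Radiation-Induced Polymerisation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates the radiation-induced free-radical polymerisation of
    methacrylic acid (MAA) in aqueous solution with a coarse-grained
    chemical-events Monte Carlo method.  Each bead is one monomer, modelled
    as an oriented cuboid; radicals appear at random locations and trigger
    activation (combination) or breakdown events whose probabilities follow
    size-dependent error-function laws fitted from quantum-chemistry data.
    Rigid-body rotation-translation moves are screened with a native
    Gilbert-Johnson-Keerthi (GJK) convex distance kernel, and infeasible
    steps are reverted.  Includes ensemble replication, growth statistics
    (backbone and polymer length), Jaccard voxel-occupancy similarity,
    subcube randomness analysis, extended-XYZ trajectory export, and
    ggplot2 visualisations.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    pracma,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo: Rcpp
Suggests:
    igraph,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
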