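Package: polyadsorb
Title: Dynamic Monte Carlo Simulation of Semiflexible Polymer Adsorption
    on a Planar Surface
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Off-lattice bead-spring simulation of a single semiflexible
    polymer adsorbing onto an attractive planar wall. Bonds follow a
    finitely extendable nonlinear elastic (FENE) potential, excluded
    volume and the monomer-surface attraction are Morse potentials, and
    chain stiffness enters through an angular bending energy. Metropolis
    single-monomer-displacement kinetics with a compiled inner loop,
    deterministic per-replica random streams, and an escape-restart rule
    provide the sampling engine. The observable suite covers monomer
    height distributions, adsorbed fraction, bond-direction spatial
    correlation, tangent-tangent correlation, surface-energy fluctuation,
    and a toroid classifier with turn counting. A sweep pipeline maps the
    partially-adsorbed to fully-adsorbed phase boundary in the plane of
    bending energy and surface attraction strength.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    ggplot2,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
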