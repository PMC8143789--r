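Package: cellpotts
Title: Cellular Potts Model Simulation Engine
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A scriptable cellular Potts model (CPM) engine for 2D lattice
    simulations of cells and tissues. Provides a modular Hamiltonian
    (differential adhesion, volume and perimeter elasticity, Act protrusion
    activity), Metropolis copy-attempt dynamics with a Monte Carlo Step
    clock, model processes (circle seeding, immutable obstacles, cell
    growth and division), a Conway Game-of-Life cellular automaton sharing
    the same lattice and output machinery, torus-aware observables
    (circular-mean centroids, heterotypic interface length, connectedness),
    PNG frame rendering, CSV statistics logging, JSON configuration files,
    declarative benchmark runners, and a scalability sweep with adaptive
    grid sizing.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    grDevices,
    graphics,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
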