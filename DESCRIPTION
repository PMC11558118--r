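Package: ssbwrap
Title: Force-Spectroscopy Thermodynamics and Coarse-Grained Wrapping
    Simulations of SSB-ssDNA Binding
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for salt-dependent binding of single-stranded
    DNA binding protein (SSB) to short ssDNA. One arm converts constant-force
    magnetic-tweezers extension traces into dwell times, Bell-model
    force-dependent binding/unbinding rates, critical forces, and null-force
    binding free energies via worm-like-chain stretch-work bookkeeping. The
    other arm builds coarse-grained topologies (C-alpha protein, three beads
    per nucleotide ssDNA), evaluates a structure-based 12-10 interface
    potential with Debye-Hueckel screened electrostatics, runs anchored
    BAOAB Langevin dynamics, and summarises wrapping by 2D potentials of
    mean force and per-frame subunit occupancy. A synthetic-data module
    generates telegraph traces with known Bell kinetics and a toy tetramer
    complex with two surface-charge states so the whole pipeline is testable
    offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    bio3d,
    jsonlite,
    yaml,
    withr,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mclust,
    optparse
Config/testthat/edition: 3
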