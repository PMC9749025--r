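Package: egressr
Title: Ligand Egress Path Discovery and Free-Energy Toolkit on Model Landscapes
Version: 0.1.0
Authors@R: person("egressr", "developers", role = c("aut", "cre"),
    email = "egressr@example.org")
Description: A desk-scale toolkit for the enhanced-sampling workflow used to
    characterise ligand unbinding from buried protein binding sites: scaled
    potential dynamics with a Ratchet&Pawl bias to discover egress channels,
    QuickBundles streamline clustering of unbinding trajectories into guess
    paths, well-tempered metadynamics on path collective variables to build
    free-energy surfaces, MEPSA-style minimum free energy path extraction on
    gridded surfaces, and restrained alchemical decoupling with Bennett
    acceptance ratio estimates and an analytic Boresch standard-state
    correction.  Every stage is exercised on configurable low-dimensional
    model energy landscapes with analytic gradients and quadrature oracles,
    so the whole pipeline is testable without molecular data.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
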