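Package: g4slip
Title: Strand-Slippage Intermediates of Parallel G-Quadruplexes by
    Well-Tempered Metadynamics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to characterise vertically strand-slipped folding
    intermediates of the parallel human telomeric G-quadruplex. Provides
    collective variables for the Hoogsteen hydrogen-bond network (Hb_core)
    and guanine pi-pi stacking density (pipi_core), enumeration and
    classification of slipped two-tetrad topologies, a well-tempered
    metadynamics engine with wall restraints driving overdamped Langevin
    dynamics on analytic model potentials, time-dependent-offset
    reweighting to reconstruct free-energy surfaces on unbiased collective
    variables, per-basin free energies with block-averaged uncertainties,
    and a synthetic-structure generator for idealised native and slipped
    G-quadruplex geometries, transition trajectories and model potentials.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    bio3d,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
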