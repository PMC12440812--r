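Package: celliq
Title: Charge Equilibration Layer for Long-Range Interactions in Graph Network Potentials
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building local graph-network interatomic potentials with a
    differentiable charge-equilibration (Qeq) layer for long-range electrostatics.
    Provides the screened-Gaussian Coulomb energy and its charge-space operator for
    open and periodic (Ewald) boundaries, a constrained Qeq solver with implicit
    differentiation, a strictly local scalar edge-network backbone, a charge
    equilibration layer that maps latent edge features to Qeq parameters and embeds
    the equilibrated charges back into the network, force-matching training with
    per-species energy shifts, an exact synthetic reference-data generator, and
    Langevin molecular dynamics with stability diagnostics. Structures are read and
    written in extended XYZ format.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
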