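Package: pnpbik
Title: Poisson-Nernst-Planck-Bikerman Theory of Ionic Solutions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Mean-field modelling of ionic solutions in which ions and water
    are finite-size particles with interstitial voids. Provides saturating
    Fermi distributions with a steric potential, fourth-order
    Poisson-Bikerman electrostatics with ion-ion and ion-water correlations,
    a one-dimensional planar double-layer solver, steady-state
    Nernst-Planck-Bikerman transport discretized with a generalized
    Scharfetter-Gummel exponential-fitting scheme, a closed-form generalized
    Debye-Hueckel model for single-ion activity coefficients, and
    atomic-scale electric and steric potentials at ion-channel binding sites
    from point-charge structures.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    yaml,
    jsonlite,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    withr,
    bio3d
Config/testthat/edition: 3
RoxygenNote: 7.3.3
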