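Package: ionpair
Title: Primitive-Model Electrolytes, Ion Pairing and Solvent-Shell
    Polarization Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for studying ion pairing in divalent metal sulfate
    solutions with implicit-solvent electrolyte models.  Implements the
    primitive model (charged hard spheres in a dielectric continuum), a
    multicomponent Ornstein-Zernike solver with the hypernetted-chain
    closure for osmotic coefficients, a canonical Metropolis Monte Carlo
    engine with Ewald electrostatics that serves as an independent
    validation route, and a fitting procedure that adjusts the cation
    hard-sphere diameter to an osmotic-coefficient curve with the anion
    diameter held fixed.  A companion analysis layer computes radial
    distribution functions, contact and solvent-shared ion-pair
    populations, coordination numbers, solvation-shell membership and
    induced-dipole statistics from particle configurations, and a
    synthetic-data layer generates configurations with planted pairing
    truth, field-aligned induced dipoles and noisy osmotic-coefficient
    curves for end-to-end testing.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    graphics,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
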