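Package: pnpcrit
Title: Critical Potentials and Flux Asymptotics for Poisson-Nernst-Planck Ion Channels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the one-dimensional steady-state Poisson-Nernst-Planck
    (PNP) model of ionic flow through a membrane channel carrying two cation
    species of a common valence and one anion species, with a small permanent
    charge on an interior segment and relaxed (nearly electroneutral) bath
    boundary conditions.  Implements the explicit singular-perturbation flux
    expansions in the permanent-charge magnitude and in the bath neutrality
    deviations, the five critical potentials (the per-species Nernst-type
    reversal potentials and two ion-coupling thresholds) that partition the
    voltage axis into regimes where a small positive permanent charge enhances
    or reduces each species' flux, a sign-regime classifier for those regimes,
    and an independent collocation solver for the full stiff boundary-value
    problem used to validate every analytic claim numerically.  Includes a
    seeded fixture generator, current-voltage curve utilities, configuration
    file input, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    yaml,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
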