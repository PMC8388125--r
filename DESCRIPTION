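Package: slpkin
Title: Kinetic and Equilibrium Analysis of Self-Labeling Protein Tags
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Mechanistic analysis of covalent labeling reactions of
    self-labeling protein tags (HaloTag7, SNAP-tag, CLIP-tag) measured by
    fluorescence polarization or anisotropy. Provides mass-action models of
    the labeling reaction (one-step irreversible, two-step binding-then-
    reaction, product aging, and kinetic competition), projection of species
    trajectories onto polarization observables, global nonlinear least-squares
    fitting across concentration series with Monte Carlo confidence
    intervals, equilibrium binding isotherms, four-parameter logistic
    competition analysis with exact depletion-corrected conversion of
    half-inhibition concentrations to dissociation constants, and a
    synthetic-data generator that emulates stopped-flow and microplate
    reader experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    minpack.lm,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
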