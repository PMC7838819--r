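Package: dnhfit
Title: Micromechanical Constitutive Modelling of Double-Network Hydrogels
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Forward simulation and parameter identification for a
    micromechanically based constitutive model of alginate-based
    double-network hydrogels ionically cross-linked by mono-, di- or
    trivalent cations. A Langevin (entropic) chain energy with a
    full-stretch cutoff is combined with an enthalpic contribution from
    fully stretched polysaccharide chains, integrated over an evolving
    chain-length population under the network alteration rule, and added
    to a two-invariant hyperelastic energy for the neutral network. The
    model predicts J- and S-shaped uniaxial stress-stretch curves with
    Mullins-type softening under cyclic loading; material parameters are
    identified from tensile data by damped least squares.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    graphics,
    grDevices,
    utils,
    tools,
    minpack.lm,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pracma,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
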