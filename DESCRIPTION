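Package: forkRPA
Title: Force-Regulated Kinetics of Single-Stranded DNA Binding Proteins at a
    DNA Fork
Version: 1.0.0
Authors@R:
    person("Felix", "Bergmann", email = "fbergmann@posteo.net",
           role = c("aut", "cre"))
Description: Analysis pipeline for magnetic-tweezers experiments probing how
    single-stranded DNA binding proteins such as replication protein A (RPA)
    open and close a DNA fork under force. Provides freely-jointed-chain and
    worm-like-chain elasticity models to convert bead extension into opened
    base pairs, a two-term Arrhenius model for the net fork opening rate with
    equilibrium-force and binding-energetics calculus, a Gillespie simulator
    of footprint-sized stepping trajectories with bead noise, chi-square step
    detection for footprint estimation, weighted nonlinear fitting of
    rate-versus-force data, and friction analysis of protein sliding driven
    by a rezipping fork.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
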