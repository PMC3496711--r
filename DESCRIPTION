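Package: fretensemble
Title: Ensemble FRET Simulation and Analysis in Dynamic and Static
    Orientational Regimes
Version: 0.1.0
Authors@R:
    person("fretensemble", "developers", role = c("aut", "cre"),
           email = "maintainer@example.org")
Description: Tools for simulating and analysing ensemble Forster resonance
    energy transfer (FRET) measurements. Provides deterministic Forster-theory
    primitives (transfer rates, efficiencies, Forster radius, spectral overlap
    integral, dipole orientation factor), Monte-Carlo population simulations of
    FRET efficiency distributions under donor-acceptor distance heterogeneity,
    long-lived acceptor dark states (blinking), and static versus dynamic
    orientational averaging regimes, a closed-form probability density for the
    transfer efficiency in the static random isotropic regime, and synthesis
    plus multi-exponential fitting of ensemble donor fluorescence decays.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
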