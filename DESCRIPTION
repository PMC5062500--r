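Package: gatekin
Title: Markov Gating Simulation and Kinetic Analysis of Allosteric Ion
    Channel Inhibition
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates and analyses patch-clamp experiments on ligand- and
    voltage-gated ion channels, built around the closed-state stabilization
    of TRPV1 by oleic acid. Provides a continuous-time Markov gating
    simulator (exact Gillespie single-channel trajectories and deterministic
    ensemble currents), half-amplitude threshold idealization of
    single-channel records, logarithmic (Sine-Sigworth) dwell-time
    histograms with exponential-mixture fitting, Boltzmann
    conductance-voltage fits, Hill dose-response fits, single-exponential
    inhibition and recovery time courses, closed-state stabilization
    energetics, and a reproducible simulate-idealize-fit pipeline with
    group statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    jsonlite,
    graphics,
    stats,
    utils
Suggests:
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
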