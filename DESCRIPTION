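Package: strandbreakr
Title: Stochastic DNA Strand-Break Induction, Clustering and Repair Kinetics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale Monte Carlo chain for radiation-induced DNA damage on a
    simplified double-helix chromatin geometry: a configurable surrogate track
    source produces stochastic energy deposits and hydroxyl-radical spawn
    points; Brownian radical chemistry with perfect histone scavenging and a
    hard diffusion time cut emits backbone encounters; direct (linear energy
    ramp) and indirect (Bernoulli) damage models score strand breaks; breaks
    are clustered, paired into double-strand breaks (DSBs) and classified by
    complexity (DSB/DSBp/DSBpp) and source (direct/indirect/hybrid/mixed);
    yields feed a mass-action ODE model of the NHEJ, HR, SSA, micro-SSA and
    Alt-NHEJ repair pathways producing remaining-DSB and gamma-H2AX foci
    time-curves, and a degree-of-protection analysis estimates the
    scavengeable DSB fraction.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    deSolve,
    jsonlite,
    rlang,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
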