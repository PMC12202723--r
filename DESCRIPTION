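Package: pcaslsim
Title: Bloch Simulation and SNR-Efficiency Optimization of PCASL Labeling at 7 T
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for designing pseudo-continuous arterial spin labeling
    (PCASL) pulse trains for SAR-constrained perfusion imaging at ultra-high
    field. Constructs the five-parameter PCASL RF and gradient pulse train,
    applies a fixed-duration minimum-SAR VERSE transform, computes
    flow-weighted labeling efficiency for pulsatile laminar flow with a
    hard-pulse Bloch integrator, simulates the static-tissue perturbation of
    aliased labeling planes, ranks parameter combinations by SNR efficiency
    under an RF-energy-proportional minimum TR, and designs adiabatic
    hyperbolic-secant background-suppression inversion pulses, including a
    SAR-capped VERSE variant, phase re-optimization, and two-pulse T1-nulling
    timing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
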