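Package: cand1cycle
Title: Kinetic Modelling of Cand1-Mediated Substrate Receptor Exchange on
    Cullin-RING Ligases
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Mass-action kinetic model of the Cand1 exchange cycle that
    distributes substrate receptors (F-box/Skp1 modules) over the Cul1
    scaffold of SCF ubiquitin ligases. Provides a thermodynamically
    consistent reaction-network builder with conservation-law elimination,
    stiff ODE simulation of complex assembly and substrate degradation,
    algebraic equilibrium solving with Jacobian eigenvalue (exchange rate)
    analysis, occupancy/exchange trade-off scans, Cand1 dose-response and
    substrate half-life pipelines, comparison of exchange-factor versus
    weak-binding network architectures, and calibration of the ternary
    complex dissociation rate against simulated FRET exchange experiments.
    Includes a synthetic-data stage (noisy observable traces, parameter
    recovery) so every estimation step is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    minpack.lm,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
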