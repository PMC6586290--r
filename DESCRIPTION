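Package: hfvoi
Title: Value of Information Analysis for Telehealth in Chronic Heart Failure
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A decision-analytic pipeline for valuing further research on
    telehealth in chronic heart failure management. Implements a five-state
    (NYHA I-IV plus death) three-arm cohort Markov model comparing usual
    care, nurse telephone support and home telemonitoring over a 20-year
    horizon in 4-month cycles, probabilistic sensitivity analysis with
    Dirichlet/beta/gamma/uniform parameter distributions, net monetary
    benefit, cost-effectiveness acceptability curves and frontiers, per
    patient and population expected value of perfect information (EVPI),
    grouped expected value of partially perfect information (EVPPI) via
    two-level nested Monte Carlo with stepwise convergence escalation, and
    a discounted effective-population projection for scaling per-patient
    value of information to the national level. A synthetic evidence
    generator emulates the statistical structure of trial-derived inputs.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    yaml,
    Rcpp,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    ggplot2,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
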