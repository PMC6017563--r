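Package: depotpkpd
Title: Pharmacokinetic-Pharmacodynamic Modelling of Sustained-Release
    Depot Formulations with Feedback Turnover Response
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Mechanistic pharmacokinetic-pharmacodynamic (PK-PD) toolkit for
    peptide drugs given as solutions or sustained-release injectable depots,
    built around the leuprolide/testosterone system in rats. Provides a
    fixed-step classical Runge-Kutta engine with bolus dosing events and
    release-lag gating; one-compartment solution models with Bateman closed
    forms; a three-section depot model (non-encapsulated, diffusive, erosive)
    with an erosive transit chain; an indirect-response turnover model for
    testosterone with an inhibitory feedback compartment and Hill drug effect;
    non-compartmental analysis including baseline-corrected positive/negative
    AUEC decomposition and exact Mann-Whitney group comparison; multi-start
    weighted least-squares estimation with AIC transit-count selection and
    residual diagnostics; and a synthetic six-group rat-study generator with
    lognormal between-subject variability for end-to-end testing.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    stats,
    utils
Suggests:
    deSolve,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
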