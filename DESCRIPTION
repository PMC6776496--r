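Package: mdahmm
Title: Partially Hidden Two-State Markov Models for Composite Minimal
    Disease Activity Outcomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Continuous-time two-state Markov modelling of Minimal Disease
    Activity (MDA), a composite clinical outcome defined by satisfying at
    least 5 of 7 criteria, under intermittent clinic observation with
    partially missing criterion components.  The MDA state is treated as
    observed at visits where the composite rule can be decided and latent
    otherwise; count-distribution emission models for the eight defining
    outcome variables let visits with incomplete information contribute to
    a full hidden-Markov likelihood.  Includes maximum-likelihood fitting
    with log-linear covariate effects on transition intensities,
    Monte-Carlo estimation of sustained (one year or longer) state
    occupancy summaries with parametric-bootstrap intervals, a two-phase
    semi-Markov (phase-type) robustness check, and a synthetic-cohort
    generator emulating the observation structure of a psoriatic
    arthritis clinic.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    Matrix,
    MASS,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
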