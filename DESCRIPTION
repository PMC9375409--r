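Package: crstand
Title: Regression Standardisation for Causal Effects with Competing Risks
Version: 0.1.0
Authors@R:
    person("crstand", "maintainers", email = "crstand@example.org",
           role = c("aut", "cre"))
Description: Fits flexible parametric (Royston-Parmar) cause-specific
    survival models on the log cumulative hazard scale, with optional
    time-dependent effects via restricted cubic splines of log time, and
    applies regression standardisation (the g-formula for point
    treatments) to estimate counterfactual total effects (cause-specific
    cumulative incidence and restricted mean failure time / expected life
    lost), controlled direct effects, and separable direct and indirect
    effects in the presence of competing events.  Differences, ratios and
    linear combinations of standardised quantities come with delta-method
    confidence intervals.  Includes Kaplan-Meier and Aalen-Johansen
    nonparametric estimators and a competing-risks simulator with known
    ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    survival,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
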