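Package: srsignal
Title: Disproportionality Signal Detection and Onset-Pattern Analysis for
    Spontaneous Adverse-Event Reports
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for pharmacovigilance signal detection in spontaneous
    reporting system databases laid out like the Japanese Adverse Drug Event
    Report (JADER) tables. Implements the Bayesian confidence propagation
    neural network information component (IC) with closed-form and
    Monte-Carlo 95% credible intervals, a women-versus-men subgroup
    disproportionality contrast (IC delta) with a three-part women-signal
    criterion, and Weibull time-to-onset fitting with hazard-shape
    classification of onset patterns. Includes a synthetic report-database
    generator with configurable true reporting-rate ratios, sex-specific
    multipliers and Weibull onset models, so that the whole pipeline can be
    exercised and validated without access to licensed source data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    fitdistrplus,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    survival,
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
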