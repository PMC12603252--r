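Package: vegrisk
Title: Dietary Health-Risk Assessment for Toxic Elements and Nitrate in
    Vegetables
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Deterministic and probabilistic dietary health-risk assessment
    for potentially toxic elements (Pb, Cd, Zn, Ni) and nitrate in vegetables.
    Computes chronic daily intake, hazard quotients and hazard indices,
    carcinogenic slope-factor risks and total carcinogenic risk per
    demographic group, with risk-band classification; propagates concentration
    uncertainty by lognormal Monte Carlo simulation; quantifies input
    importance with variance-based Sobol sensitivity analysis (Saltelli
    cross-sampling, first-, second- and total-order indices); interpolates
    site-level concentrations onto regular grids by inverse distance
    weighting; and generates calibrated synthetic site-concentration tables
    so the whole pipeline is testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    lhs,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
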