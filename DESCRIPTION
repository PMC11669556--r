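Package: dbnpanel
Title: Discrete Dynamic Bayesian Networks for Longitudinal Categorical Panel Data
Version: 0.1.0
Authors@R:
    person("dbnpanel", "maintainers", email = "maintainers@dbnpanel.invalid",
           role = c("aut", "cre"))
Description: Tools for building, learning and querying discrete dynamic
    Bayesian networks on longitudinal categorical panel data. Provides a
    temporal network representation with lagged arcs and variables that
    enter the panel late, exact inference by variable elimination
    (posteriors, smoothing, soft evidence, record log-likelihood and
    anomaly scoring), maximum-likelihood and EM parameter learning with
    missing data, constraint-based structure learning with the PC
    algorithm under temporal tiering and expert constraints, MAP /
    most-probable-explanation queries, do-operator interventions and
    best-/worst-case scenario analysis, information-theoretic feature
    ranking and value of information, a seeded synthetic cohort generator
    emulating a five-wave child-nutrition panel, and an end-to-end
    pipeline with a command-line entry point.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
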