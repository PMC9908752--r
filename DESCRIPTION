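Package: pppgame
Title: Tripartite Evolutionary Game Analysis of Public-Private Partnership
    Regulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models the regulation of public-private partnership (PPP)
    projects for combined medical and elderly-care services as a
    three-population evolutionary game between the private operator, the
    government regulator and the monitoring public.  Provides the 2x2x2
    payoff table, replicator dynamics in closed form and via an
    independent payoff-table route, switching functions and critical
    thresholds, Jacobian-based stability classification of the eight
    pure-strategy equilibria (evolutionary stable strategy detection),
    numerical integration of trajectories, ensemble runs, and the
    parameter-sensitivity sweeps used to study how subsidies, penalties,
    regulation costs and monitoring incentives shape convergence to the
    all-cooperate outcome.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    ggplot2,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
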