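Package: ppcea
Title: Markov Cohort Cost-Utility Model for Long-Acting Injectable
    Antipsychotics in Schizophrenia
Version: 0.1.0
Authors@R:
    person("ppcea", "maintainers", email = "ppcea@example.org",
           role = c("aut", "cre"))
Description: A five-state Markov cohort model for cost-utility analysis of
    paliperidone palmitate one-month (PP1M) and three-month (PP3M)
    long-acting injectables against extended-release oral paliperidone (ER)
    in schizophrenia, from a healthcare-system perspective.  Provides
    rate-to-probability conversion under a constant-hazard assumption,
    a half-cycle-corrected discounted cohort trace with an individual-level
    microsimulation oracle, incremental cost-effectiveness analysis (ICER,
    net monetary benefit, dominance and willingness-to-pay verdicts),
    one-way (tornado) sensitivity analysis, probabilistic sensitivity
    analysis with method-of-moments Beta/Gamma fits, cost-effectiveness
    acceptability curves, scenario sweeps over drug price, hospitalization
    cost and time horizon, and a synthetic parameter-set generator for
    property testing.  All reference inputs ship as an embedded fixture.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
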