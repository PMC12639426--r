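Package: nof1ppgr
Title: Series-of-N-of-1 Analysis of Postprandial Glycemic Responses to Staple Foods
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Design, simulation and Bayesian analysis tools for series-of-N-of-1
    crossover trials of postprandial glycemic responses. Provides available-
    carbohydrate portion standardization and per-period randomization for
    multi-food crossover designs; extraction of the postprandial blood glucose
    peak (PBGP) and 3-h incremental area under the curve (iAUC) from continuous
    glucose monitoring traces; blocked Gibbs samplers for the individual-level
    linear model and the population-level hierarchical (random-effects) model
    with split-chain Gelman-Rubin diagnostics; minimum clinically important
    difference (MCID) posterior-probability decision rules and the CV-weighted
    glycemic response score (WGRS); and a simulation-based power and sample-size
    study for the series-of-N-of-1 design, driven by a synthetic-data generator
    that emulates the trial's stated variance structure.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
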