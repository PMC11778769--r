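Package: ceatree
Title: Decision-Tree Cost-Effectiveness Analysis of Smoking-Cessation Strategies
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Evaluates stratified sequential decision-tree models for the
    cost-effectiveness of smoking-cessation strategies delivered in primary
    care. Cohorts are stratified by nicotine dependence (Fagerstrom index),
    each stratum receives an ordered sequence of counselling and
    pharmacotherapy stages, and strategies are compared by incremental
    cost-effectiveness ratios with simple and extended dominance pruning.
    Includes one-way (tornado) sensitivity analysis, probabilistic
    sensitivity analysis with moment-matched Beta and Gamma parameter
    distributions, cost-effectiveness acceptability curves, a YAML
    configuration format with a packaged base-case parameter set, and a
    synthetic scenario generator for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite,
    tibble,
    dplyr,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
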