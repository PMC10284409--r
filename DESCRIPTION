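Package: sabvpower
Title: Monte-Carlo Power Analysis for Sex-Inclusive 2x2 Factorial Designs
Version: 0.1.0
Authors@R: person("Analysis", "Pipelines", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulation-based power analysis for in vivo studies that include
    both sexes in a balanced 2x2 (sex by treatment) factorial design. Provides
    a scenario-based generator of balanced normal datasets (baseline sex
    difference, same-direction treatment-by-sex interaction, one-sex-only
    effect, opposite effects), three analysis pipelines (factorial linear
    model with within-sex post-hoc contrasts, pooled two-sample t test,
    per-sex disaggregated t tests) plus a single-sex design comparator, and a
    Monte-Carlo engine that estimates statistical power for every model term
    with Wilson confidence intervals, alongside a closed-form noncentral-t
    power oracle, tidy CSV/JSON export, power-curve plots and a command-line
    interface.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite,
    ggplot2,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
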