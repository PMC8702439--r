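Package: affdisc
Title: Incidental Affect and the Disjunction Effect in Intertemporal Choice
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for two-group studies of how
    incidental affect shifts intertemporal choice when one option is
    immediate.  Implements the adaptive bisection staircase titration task,
    a synthetic-cohort generator with power-law subjective time perception,
    hierarchical Bayesian estimation of hyperbolic discount rates (joint and
    condition-split, on objective or subjective time), WAIC model comparison
    with Gelman-Rubin convergence diagnostics, and the group-level
    frequentist layer (mixed-design ANOVA with Bonferroni post-hocs, t tests
    with Cohen's d, 2x2 chi-square with effect size r).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    rjags,
    jsonlite,
    stats,
    utils
Suggests:
    car,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
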