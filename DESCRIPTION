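Package: cdcem
Title: Cost-Effectiveness Modelling of Biologic Therapy in Crohn's Disease
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A two-phase health-economic model of biologic therapy in
    moderate to severe Crohn's disease: a decision-tree induction phase
    followed by a Markov cohort maintenance phase over two-week cycles and
    a lifetime horizon. Provides constrained least-squares calibration of
    CDAI-state transition matrices against end-of-maintenance target
    distributions, societal-perspective cost and QALY accrual with
    discounting, incremental cost-effectiveness analysis with dominance
    handling, one-way and structural scenario analysis, and probabilistic
    sensitivity analysis with cost-effectiveness acceptability curves.
    Ships the published Swedish model inputs as packaged fixtures, a
    synthetic-input generator for the unpublished parameters, and an
    individual-level microsimulation used to validate the cohort engine.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
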