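Package: heeprev
Title: Health-Economic Evaluation of Family-Based Diabetes Prevention
    Interventions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A decision-analytic front end and an 11-state, 70-cycle Markov
    cohort model for the long-term cost-effectiveness evaluation of school-
    and family-based lifestyle interventions preventing type 2 diabetes.
    Converts trial-measured effects (weight-status relative risk reductions,
    or reductions in energy balance-related behaviours) into adult
    weight-status distributions, simulates disease incidence, mortality,
    discounted QALYs and costs (including friction-cost productivity losses),
    and computes ICERs, one-way (tornado) and probabilistic sensitivity
    analyses, and payer-perspective budget impact with triennial
    re-implementation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
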