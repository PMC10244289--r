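Package: gdmcea
Title: Lifetime Cost-Effectiveness of Antenatal Lifestyle Intervention for
    Gestational Diabetes Prevention
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Decision-analytic Markov life-table model evaluating the lifetime
    cost-effectiveness and return on investment of a structured antenatal
    lifestyle (diet and/or physical activity) intervention that reduces the
    incidence of gestational diabetes mellitus (GDM) and subsequent progression
    to type 2 diabetes. Provides a validated parameter-bundle data model with
    CSV readers and writers, a synthetic input generator for fully reproducible
    testing, epidemiological rate machinery (relative-risk adjustment for
    population prevalence, incidence decomposition, background-mortality
    subtraction, Poisson spline rate smoothing), a three-state cohort Markov
    engine with half-cycle correction and discounting, health-economic outputs
    (QALYs, cost categories, ICER with dominance handling, ROI, efficiency
    frontier with extended dominance), and deterministic, probabilistic and
    threshold sensitivity analyses.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    generics,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    splines,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
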