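Package: c4wue
Title: C4 Leaf Gas Exchange, Stomatal Limitation, and Whole-Plant Water Use
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing leaf- and whole-plant water-use efficiency in
    C4 crops. Fits the enzyme-limited C4 A/ci response model to estimate the
    apparent maximum PEPC carboxylation rate (Vpmax) and the CO2-saturated
    asymptote (Vmax), solves the coupled stomatal supply-demand operating
    point, and derives stomatal limitation, the A/ci inflection point, and
    intrinsic water-use efficiency. Includes gravimetric dry-down water
    budgeting (relative soil water content and daily water use), stomatal
    patterning summaries (field-of-view densities and complex sizes), the
    associated statistical layer (one-way, two-way and repeated-measures
    ANOVA, Tukey HSD with letter displays, least-squares means, planned
    contrasts), and a seeded synthetic-data generator emulating a greenhouse
    phenotyping experiment so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    readr,
    ggplot2,
    generics,
    stats,
    utils,
    emmeans,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
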