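Package: floodr
Title: Neutrophil Cytometry Cohort Simulation, Gating and Control-Anchored
    Response Modelling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying the systemic neutrophil compartment in
    repeated-measures flow cytometry cohorts. Provides a seeded synthetic
    cytometry cohort generator (log-normal subset mixtures with subject-level
    random effects), FCS 3.0 and delimited-text event input/output, quadrant
    gating of CD16/CD62L neutrophil subsets with conversion of gated fractions
    to blood concentrations, repeated-measures ANOVA with Tukey contrasts and
    fold-change confidence intervals, and a control-anchored PCA response
    model for single cells with explained response-specific variance,
    80 percent benchmark ellipses, overlap statistics and loading biplots.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    emmeans,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
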