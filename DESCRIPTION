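Package: qofprev
Title: Smoking Prevalence Estimation from QOF Pay-for-Performance Data
Version: 0.1.0
Authors@R:
    person("qofprev", "maintainers", email = "maintainers@example.org",
           role = c("aut", "cre"))
Description: Estimates smoking prevalence in English general-practice
    populations from published Quality and Outcomes Framework (QOF)
    indicator numerators and denominators, aggregates practice estimates
    to local-authority districts, quantifies agreement between paired
    prevalence estimates (Pearson correlation, Lin's concordance
    correlation coefficient, Bland-Altman limits of agreement, calibration
    regression with outlier removal), and fits negative binomial models of
    premature coronary heart disease mortality counts with and without the
    prevalence estimate. Includes a synthetic QOF-like registry generator
    with known ground truth for bias and parameter-recovery studies, and a
    file-based pipeline with a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    MASS,
    stats,
    utils,
    graphics,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
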