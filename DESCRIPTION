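Package: efrd
Title: Evidence Factors for Fuzzy Regression Discontinuity Designs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds nearly independent evidence factors from a fuzzy
    regression discontinuity design with sequential treatment assignments.
    Subjects are stratified on discrete covariates, a local-randomization
    window is selected by covariate balance, and each level of the
    assignment process (eligibility, receipt, use, ...) yields a stratified
    Wilcoxon rank-sum comparison tested by randomization inference. The K
    factor p-values are combined into one valid p-value from the q largest
    order statistics (Fisher or truncated product), and each factor admits
    a Rosenbaum-style sensitivity analysis bounding its p-value under a
    per-level unmeasured bias parameter Gamma. A simulator reproduces the
    validity and power study for one-sided (K = 3) and two-sided (K = 2)
    non-compliance designs.
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
    grDevices,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
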