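Package: expectband
Title: Observed-Versus-Expected Monthly Measurement Rates with Composite
    Expectation Bands
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying disruption and recovery in routine
    healthcare activity from monthly event rates. Curates record-level
    measurement data into per-1,000 monthly rates by demographic subgroup,
    fits a quasi-Poisson trend model with cyclic P-spline seasonality and a
    linear long-term trend via penalized iteratively reweighted least
    squares, projects two counterfactual expectations (continued trend and
    frozen trend) beyond a reference month, combines them into a composite
    expectation band, and summarizes absolute and relative deviations per
    month and over reporting periods. Includes a synthetic primary-care
    data generator with known ground truth for end-to-end validation.
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
    splines,
    stats,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    mgcv,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
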