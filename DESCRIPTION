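Package: prestonloss
Title: Preston-Curve Projections of Pandemic-Attributable Progress Loss in Health SDG Indicators
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates extended Preston curves (log-log panels of health-related
    Sustainable Development Goal indicators on per-capita GDP, the Gini index and
    health expenditure, with country and period fixed effects and region-specific
    GDP elasticities), extrapolates each fitted curve yearly to 2030 under paired
    pre- and post-pandemic GDP growth scenarios, and computes direction-aware
    potential-progress-loss statistics aggregated by health theme, World Bank
    income group and country. A synthetic-world generator reproduces the panel
    structure the model assumes so the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
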