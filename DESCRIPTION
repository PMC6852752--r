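Package: biosimsavings
Title: Biosimilar Uptake and Cost-Savings Analysis from Drug Purchase Audits
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for estimating realized and potential
    (unrealized) cost savings from biosimilar substitution using drugstore
    and hospital purchase-audit records. Reads validated purchase tables
    (region, sector, month, product, dollars, units), matches originator
    and biosimilar products at the dosage-form and strength level, computes
    pooled and province-stratified unit prices and price discounts,
    realized/unrealized savings under both aggregation conventions,
    relative market-share scenario tables, eligibility sensitivity
    analyses, and quarterly biosimilar uptake series. Includes a
    configurable synthetic purchase-audit generator so every stage is
    testable without proprietary audit data, plus packaged national
    aggregates for the Canadian infliximab, filgrastim and insulin
    glargine markets (July 2016 to June 2018).
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
    tibble,
    tidyr
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
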