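Package: cpdenrich
Title: Enrichment and Coverage Analysis of Consumer Purchase Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for turning raw digital-receipt data into analysable
    exposure profiles. Matches purchased products to barcode-keyed (GTIN)
    specific product databases and to a regex-annotated generic food
    database with a transparent scoring algorithm, compares nutrient
    values across sources with a modified relative-difference statistic,
    quantifies how individual purchase profiles distort when only a
    subset of retailers contributes data, and ships a seeded synthetic
    cohort generator with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    stringr,
    readr,
    rlang,
    jsonlite,
    yaml,
    ggplot2,
    generics,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
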