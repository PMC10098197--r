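Package: bovamu
Title: Dose-Based Quantification of Antimicrobial Usage in Dairy Herds
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Farm-level quantification of antimicrobial usage (AMU) in adult
    bovines from treatment-event records and empty-container ("bin method")
    deposits. Resolves commercial drug products into active-ingredient masses
    with combination-drug rules, computes dose-based exposure metrics (animal
    daily dose ADD, nADD, used daily dose UDD, UADD, nUADD, and the
    antimicrobial drug use rate ADUR per 1000 animal-days), classifies dosing
    adequacy from UDD/DDDkg ratios, categorizes substances by WHO critical
    importance, and aggregates herd-, condition- and class-level summary
    tables. Includes a synthetic-data generator emulating a 38-herd,
    1010-animal year-long surveillance design and a deterministic reference
    dataset for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    readr,
    rlang,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    ggplot2,
    optparse,
    withr
Config/testthat/edition: 3
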