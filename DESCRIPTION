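Package: hwforecast
Title: Markov Cohort Forecasting of Health Facilities and Workforce Requirements
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Forecasts the number of healthcare facilities across an ordered
    ladder of workload categories with a deterministic discrete-time Markov
    cohort model, and translates the projected facility mix into year-by-year
    health-workforce requirements using staffing norms. Includes estimation of
    adjacent-upward transition probabilities from facility-category panel data,
    scenario-based 95% predictive intervals obtained by simultaneously shifting
    all transition probabilities to their confidence limits, staff-availability
    ratio (gap) analysis, and a seeded synthetic-data generator that emulates
    the facility panel, staffing-norms matrix, population series and employment
    roster the pipeline consumes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    readr,
    ggplot2,
    generics,
    jsonlite,
    withr,
    yaml,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
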