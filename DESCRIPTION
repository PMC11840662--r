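Package: oilscape
Title: Diet-Driven Land Allocation and Land-Use-Change Emissions for Vegetable Oils
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Projects 2050 global food demand for palm, soybean, sunflower and
    rapeseed oil under current and EAT-Lancet consumption rates with graded
    palm-oil replacement, allocates that demand to land through a pixel-level
    greedy prioritization over crop suitability and attainable yield, and
    converts the resulting land-use change into annualized CO2 emissions from
    forest and orchard biomass loss, peat drainage, and the oil-palm regrowth
    sink. Includes a synthetic-landscape generator so the full pipeline runs
    end-to-end on reproducible in-memory worlds, plus staple-crop displacement
    accounting and ggplot2 summaries.
License: MIT + file LICENSE
Encoding: UTF-8
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
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
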