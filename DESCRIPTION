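Package: greenozone
Title: Urban-Greening Biogenic Emissions, Ozone Exposure, and Attributable Mortality
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A tidy analysis pipeline linking urban-greening vegetation to
    ozone health burden. Fuses fine urban land cover with coarse plant
    functional type (PFT) data, assigns leaf area index, computes MEGAN-form
    biogenic isoprene emission fluxes and seasonal budgets, derives MDA8
    ozone exposure metrics from paired scenario fields (with and without
    urban biogenic emissions), and estimates ozone-attributable mortality
    with urban-greening attribution via a log-linear relative-risk model.
    A synthetic-data module generates all pipeline inputs with known
    injected structure so every stage runs and is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    tibble,
    rlang,
    ggplot2,
    generics,
    readr,
    stats,
    utils,
    jsonlite,
    yaml,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
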