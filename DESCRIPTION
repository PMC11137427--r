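Package: teleco2
Title: Carbon Accounting for Avoided Travel in US Telemedicine Sessions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An analysis pipeline estimating the net carbon dioxide emissions
    savings attributable to US telemedicine. Session records are filtered by
    clinical-encounter inclusion rules, stratified by region, session length,
    day class and hour class, and proportionally sampled; round-trip car
    travel between patient and provider is estimated through a pluggable
    routing contract; per-session savings (avoided vehicle-miles times a
    tailpipe emission factor) are netted against the energy cost of
    videoconferencing and extrapolated to national annual totals from payer
    share. A seeded synthetic-data generator reproduces the statistical
    structure of platform session data so the full pipeline is testable
    without proprietary records or live routing services.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    geosphere,
    ggplot2,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
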