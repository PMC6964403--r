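Package: airsusc
Title: Population Susceptibility to Ambient Ozone and Fine Particulate Matter
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates the fraction of a population that is more susceptible
    to the health effects of ground-level ozone and fine particulate matter
    (PM2.5) by sequentially applying age-stratified risk-factor prevalences
    (young and old age, chronic disease, pregnancy, outdoor work, low
    socio-economic status, inadequate vitamin C intake) within ten canonical
    age bands, assuming independence between factors so that no person is
    counted twice. Includes survey-weighted prevalence estimation from
    microdata, pregnancy point-prevalence from annual event counts, zonal
    multi-year averaging of gridded pollutant surfaces, quartile
    cross-classification of regional susceptibility against exposure with
    identification of priority (double-jeopardy) regions, rank-correlation
    summaries, and a seeded synthetic-data generator that emulates the
    survey, demographic, and exposure inputs for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    yaml
Config/testthat/edition: 3
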