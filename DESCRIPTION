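Package: phenocirc
Title: Circular Statistics for Herbarium-Based Plant Phenology
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools to analyse long-term reproductive phenology from digitized
    herbarium specimen records. Cleans and deduplicates occurrence records,
    encodes collection dates as circular data (one 30-degree arc per month),
    fits and ranks the ten Schnute-Groot von Mises mixture models by maximum
    likelihood, tests seasonality with Rayleigh or Hermans-Rasson uniformity
    tests chosen from the best-fit modality, compares time intervals with a
    two-sample Watson U2 test for grouped (monthly) data, and relates
    phenophase timing to lagged monthly climate (photoperiod, temperature,
    precipitation) through collinearity-screened backward-selected multiple
    regression. A seeded synthetic-data module generates specimen sets and
    climate series with known ground truth so every pipeline stage is
    testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    geosphere,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    car
Config/testthat/edition: 3
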