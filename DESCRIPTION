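Package: agrochill
Title: Agroclimatic Chill, Heat and Winter Extreme-Event Metrics for
    Fruit-Growing Regions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Seasonal chill accumulation (Utah chill units and Dynamic-model
    chill portions), heat accumulation (Richardson and Anderson growing degree
    hours), and weekly probabilities of frost and abnormal winter-heat events
    for networks of hourly weather stations, with a station completeness
    screen, an idealized daily-to-hourly temperature curve for climate-model
    projections, GCM-ensemble scenario metrics, station classification by
    chill level, and inverse-distance-weighted climate surfaces with a
    distance validity mask.  Includes a synthetic multi-station weather
    generator emulating a Mediterranean warm-to-cold station network so that
    the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    geosphere,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
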