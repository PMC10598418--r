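Package: trossa
Title: Gillnet Bycatch Rates, Deterrent Trials and Depth-Restriction
    Scenarios
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing seabird and marine mammal bycatch in
    demersal gillnet fisheries at the level of the trossa, the tier of
    gillnets that is the unit of fishing effort in the Icelandic lumpfish
    fishery.  Provides effort-standardised catch and bycatch rates per
    trossa-day, a depth-matched paired bootstrap estimating the effect of
    above-water deterrent devices on catch and bycatch, extrapolation of
    fleet-wide seabird bycatch from national landings statistics, and
    simulation of depth-based fishing restrictions with effort
    redistribution.  A synthetic fleet generator with known ground truth
    supports calibration and power checks of the estimators.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
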