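Package: slowzone
Title: Compliance Monitoring and Effectiveness of Voluntary Vessel Slow-Down Measures
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to monitor shipping-industry compliance with voluntary
    ship-strike mitigation measures (a speed reduction area, a no-go area and
    a recommended route) and to assess their effectiveness at reducing the
    risk of lethal collisions with baleen whales. Includes AIS track cleaning
    and transit segmentation, conversion of speed over ground to speed through
    water against a gridded surface-current field, a portfolio of seven
    compliance indicators built on distance-weighted average speed, linear
    mixed-model inference on transit speeds, a two-anchor speed-lethality
    logistic, gridded co-occurrence risk maps with before/after percent risk
    reduction, and a synthetic-data generator that emulates the statistical
    structure of coastal AIS archives (tidal currents, speed-dependent
    reporting rates, partial compliance behaviour).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    geosphere,
    jsonlite,
    lme4,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
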