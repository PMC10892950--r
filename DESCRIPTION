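Package: triseason
Title: Season-Level Training Analysis for Endurance Triathletes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to analyse a full training season of a short-distance
    triathlete: detection of ventilatory thresholds (Davis criteria) and
    lactate thresholds (fixed-rise rules) from incremental cycling, running
    and swimming tests; construction of eight-zone, three-phase training
    intensity models anchored at the thresholds; ECO training-load scoring
    (minutes-in-zone times a zone score and a discipline factor); weekly and
    season aggregation of load, training-intensity distribution (TID) and
    the polarization index; ISAK-based body-composition estimation (Withers
    density equation, Lee skeletal-muscle model) and its season evolution;
    and test-to-test percent-change comparison tables. A synthetic-season
    generator produces gas-exchange traces, lactate curves, training logs
    and anthropometric series with known planted truth so that every
    analysis stage can be validated by plant-and-recover studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    ggplot2,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
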