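Package: saltgraze
Title: Spatio-Temporal Overlap of Grazing Cattle and Ground-Nesting Birds
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Quantifies the spatio-temporal overlap between free-roaming
    grazing cattle and ground-nesting shorebirds on saltmarshes. Builds
    gridded cattle-activity surfaces from GPS collar fixes, computes weekly
    range and habitat-use metrics (CA100, zone activity shares, 95th
    percentile distance to the sea wall), fits AR(1) generalized least
    squares trend models with backward single-term elimination, converts
    dummy-nest trampling trials into daily and incubation-length trampling
    probabilities, fits a smooth binomial dose-response of trampling risk on
    cattle activity, and projects it into per-cell 24-day nest-trampling risk
    maps. A seeded synthetic-data module generates marsh geometry, herd
    tracks and trampling trials so the whole analysis runs without field
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    nlme,
    mgcv,
    jsonlite,
    xml2,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
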