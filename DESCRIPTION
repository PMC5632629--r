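Package: divetyper
Title: Dive Detection, Classification and Activity Budgets from 1-Hz
    Time-Depth Records
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing archival tag records from deep-diving
    cetaceans. Detects dives in 1-Hz depth series, partitions each dive into
    descent, bottom and ascent phases with shoulder correction, attaches
    GPS-derived locations by nearest-fix assignment and linear interpolation,
    computes twelve per-dive behavioural metrics (including distance to the
    seafloor against a bathymetry grid), classifies dives with principal
    components analysis and Ward hierarchical clustering validated by
    bootstrap Jaccard stability, builds per-animal activity budgets and
    hexagonal dive-density grids, and classifies satellite-transmitted dive
    summaries against archived dive-type quartiles. Includes a synthetic
    deployment simulator that generates depth series, surface tracks, GPS
    fixes, bathymetry and transmitted dive summaries with ground-truth dive
    types for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    geosphere,
    jsonlite,
    stats,
    utils
Suggests:
    mclust,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
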