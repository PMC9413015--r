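Package: wristpa
Title: Acceleration Summary Measures and 24-Hour Activity Profiling from
    Wrist-Worn Accelerometry
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Processes raw tri-axial wrist acceleration streams into
    per-minute physical-activity and sleep profiles. Implements four
    acceleration summary measures (ENMONZ, MAD, the Activity Index, and
    ROCAM, the rate-of-change acceleration movement), anti-aliased FIR
    down-sampling across the 10-100 Hz actigraphy range, non-wear and
    sleep segmentation, interpretable threshold-based classification of
    each minute into sleep and sedentary/light/moderate/vigorous
    physical activity, density-initialized threshold optimization,
    random-forest fusion of the per-measure estimates, and
    leave-one-participant-out evaluation statistics. Ships a synthetic
    tri-axial day generator so the whole pipeline is testable without
    real recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    randomForest,
    Rcpp,
    signal,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
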