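Package: airwayrpa
Title: Epiglottis Airway Obstruction Ratios from Endoscopy Frames via
    Region-Puzzle Merging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies epiglottis airway obstruction in rhino-laryngoscopy
    frame sequences. Frames are reduced to colour regions by median-cut
    quantization, the epiglottis (EP) region and the airway field-of-view
    (AE) region are assembled by a seeded region-puzzle merging algorithm
    guided by per-frame detector bounding boxes, frame runs with a stable
    endoscope view are segmented into periods, abnormal frames are filtered
    by neighbour-consistency and backward-difference spike rules, and a
    continuous per-frame obstruction-ratio series (0-100 percent, 0.1
    percent granularity) is reported relative to each period's maximum
    airway area. Includes a phantom-sequence generator with exact ground
    truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    igraph,
    jsonlite,
    png,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
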