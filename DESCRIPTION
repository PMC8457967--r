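Package: chromaflock
Title: Color-Threshold Segmentation and Activity Analysis for Floor-Reared Broilers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for monitoring the activity of floor-reared broiler flocks
    from top-view pen imagery and environmental sensor logs. Learns per-channel
    color thresholds (YCbCr Cb, CIELAB b*, YIQ Q) from labeled patches to
    separate broiler bodies from litter and feeders, refines per-frame binary
    masks morphologically, accumulates hourly occupancy heat maps, computes a
    band-ratio activity index, aggregates ammonia/temperature/humidity readings
    to per-period means with a temperature-humidity index (THI), and relates
    activity to the environment through Kendall rank correlation. Includes a
    seeded synthetic scene and environment generator so the whole pipeline is
    testable without farm footage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    png,
    purrr,
    readr,
    rlang,
    tibble,
    tidyr,
    withr,
    yaml,
    EBImage,
    stats,
    grDevices,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
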