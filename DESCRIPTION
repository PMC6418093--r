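Package: arenaActivity
Title: Real-Time Group Locomotor Activity Counting for Multi-Animal Arena Videos
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Counts moving animals per circular arena region of interest in
    overhead video, without tracking identities, using K-nearest-neighbour
    background/foreground segmentation followed by Gaussian-blur and
    morphological consolidation and connected-component counting. Schedules and
    stamps optogenetic pulse-train or continuous (e.g. ethanol vapour) stimulus
    epochs onto the per-frame activity series, writes one CSV per region, and
    provides the downstream analysis used for group-activity experiments:
    time-base alignment, binning, startle normalisation by subtraction, window
    contrasts, replicate averaging, and accuracy evaluation against ground
    truth. A built-in simulator renders ground-truthed arena videos (move/pause
    random walkers drawn as dark discs on a bright diffuse background) so the
    whole pipeline is testable end to end without hardware.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    graphics,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
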