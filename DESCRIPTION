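Package: hoverpause
Title: Detection of Flapping Pauses in High-Speed Video of Hovering
    Hummingbirds
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to detect and quantify intermittent hovering --- episodic
    wing-flapping pauses --- in high-speed video of hovering hummingbirds.
    The apparent bounding box of a tracked bird oscillates with wing phase;
    the Jaccard (intersection-over-union) coefficient between boxes in
    consecutive frames therefore oscillates while the bird flaps and
    plateaus near one while the wings are held still. Pauses are segmented
    by thresholding the derivative of the Jaccard time series and extracting
    plateaus, and detections are scored against expert annotations with
    event-level precision, recall and F1. The package includes a pluggable
    frame detector (reference implementation: median-background subtraction
    with 8-connected blob extraction), a greedy IoU tracker with an
    appearance-feature hook, per-video pause statistics (pause frequency per
    wingbeat, mean pause duration, spectral wingbeat-frequency estimation),
    a fully ground-truthed synthetic hovering-bird simulator (box-sequence
    and rendered-frame tiers), CSV/JSON interchange formats and diagnostic
    plots.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    graphics,
    grDevices,
    BiocGenerics,
    IRanges,
    igraph,
    jsonlite,
    png,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    tiff,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
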