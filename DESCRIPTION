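Package: betaguide
Title: Signal-to-Background Discrimination for Beta-Probe Radioguided Surgery
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for intraoperative count-rate classification with
    beta-particle surgical probes. Implements a background-referenced
    cutoff built from a flat (uniform) model of the background count
    stream, two detection conditions on per-second sample counts (a
    minimum fraction above cutoff and a minimum contiguous run above
    cutoff), grid-search optimization of the three algorithm parameters
    via ROC curves with nearest-to-ideal selection, district-balanced
    train/test evaluation against pathology, and fixed
    signal-to-background-ratio comparators. Includes radioactive-decay
    correction of count streams, delimited-text readers and writers for
    probe data, and a Poisson count-stream simulator that emulates the
    structure of clinical acquisitions for testing and benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports: stats, utils, graphics, grDevices
Suggests: testthat (>= 3.0.0), pROC, jsonlite
Config/testthat/edition: 3
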