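Package: digdive
Title: Quantification of Larval Dig-and-Dive Behavior in Hydrogel Chambers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying the digging and diving behavior of
    Drosophila larvae confined to a vertical hydrogel chamber. Provides a
    semi-Markov behavioral simulator with ground-truth labels and a frame
    renderer, centroid tracking by median-background subtraction, behavioral
    mode classification from kernel-density-derived depth thresholds,
    dive-event extraction with cohort summaries and sliding-window mode
    probabilities, and the statistical procedures used in dig-and-dive
    studies (normality-gated test selection, rank-based comparisons with
    compact letter displays, noncentral-t power analysis, and assay index
    formulas).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    tools,
    yaml,
    jsonlite,
    tiff,
    png,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    nortest,
    igraph,
    optparse
Config/testthat/edition: 3
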