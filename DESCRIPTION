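Package: isletscope
Title: Longitudinal Quantification of Insulin Content in Pancreatic Islets
    from Fluorescence Time-Lapse Imaging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Pipeline for quantifying glucose-stimulated insulin secretion
    from tiled, burst-captured 12-bit fluorescence time-lapse images of the
    pancreas, using a fluorescent C-peptide reporter as a proxy for stored
    insulin.  Covers blur-free frame selection from rapid-fire bursts,
    phase-correlation tile stitching, rolling-ball background subtraction
    with mask-based integrated-density morphometry, optimal-assignment
    tracking of islets across time points, and per-islet percent-change and
    population heterogeneity statistics.  Includes a synthetic acquisition
    simulator with complete ground truth (label maps, per-islet content
    traces, tile offsets, blur flags) for validating every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    tiff,
    jsonlite,
    igraph,
    ggplot2,
    stats,
    utils,
    grDevices,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
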