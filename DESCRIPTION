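Package: redoxtrack
Title: Single-Cell roGFP Redox Quantification and Cell-Fate Tracking
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Ratiometric quantification of roGFP oxidation degree (OxD) in
    single cells, from flow-cytometry event streams and from multi-channel
    time-lapse microscopy. Implements the full analysis chain: calibration
    against fully reduced (DTT) and fully oxidized (H2O2) references,
    roGFP-positive gating, detection of 'oxidized' and 'reduced'
    subpopulations in bimodal OxD distributions, dose and time courses of
    the oxidized fraction, Sytox-based dead-fraction estimation and the
    linear death-versus-oxidation model, an image pipeline (drift
    registration, bit-depth normalization, background subtraction, masking,
    pixel-wise OxD, watershed segmentation, shape filtering), centroid
    tracking with optimal frame-to-frame assignment, Sytox fate calling,
    and a logistic cell-fate model that extracts an OxD death threshold.
    A synthetic-data generator produces event tables and time-lapse stacks
    with known ground truth so every stage is verifiable without raw data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    jsonlite,
    yaml,
    tiff,
    mclust,
    igraph,
    EBImage
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
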