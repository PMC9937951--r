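Package: chromoquant
Title: Scribble-Calibrated Quantification of Chromogenic Staining in
    Brightfield Tissue Sections
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Semi-automatic counting of chromogen-positive cells (such as
    SA-beta-galactosidase stained senescent cells) in RGB brightfield images
    of tissue sections. Per-class colour statistics are calibrated from
    scribble-annotated reference images, the tissue region and its convex
    hull are segmented from the background, positive pixels are grouped into
    blobs, filtered by a roundness (isoperimetric quotient) cutoff and
    counted, and per-image densities are reported. Includes diagnostic
    overlay rendering, a batch runner with a plain-text record format, a
    command-line interface, and a synthetic stained-section generator with
    ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    grDevices,
    jpeg,
    jsonlite,
    png,
    Rcpp,
    stats,
    tibble,
    tools,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
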