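Package: cellncc
Title: Optimized Normalized Cross-Correlation Cell Counting for Lensless Blood-Sample Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Counts cells in lensless (in-line holographic) blood-sample images by
    normalized cross-correlation (NCC) template matching against a library of cell
    image patches. Implements the full counting pipeline (per-template correlation
    surfaces, max-over-library, threshold marking, cluster counting) together with
    two evaluation-cost optimizations: influence-based pruning of duplicated or
    similar library templates under a loss budget, and periodic skip patterns for
    sparse sliding-window evaluation with an analytic cluster detection-probability
    model. A linear count-versus-threshold model supports threshold compensation of
    the accuracy loss these optimizations introduce. A seeded synthetic scene
    generator with ground truth makes every stage testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    png,
    tiff,
    stats,
    utils,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
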