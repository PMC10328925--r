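Package: morphomig
Title: Morphomigrational Description of Single Migrating Cells
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Joint quantification of cell shape and motion from time-lapse
    sequences of binary masks of single migrating cells. Fits the ellipse of
    identical second moments to each mask and derives, per frame, the signed
    morphomigrational angle (sMM) between the major axis and the centroid
    displacement, major-axis dynamics, turning angle and elongation. Numeric
    descriptors are mapped onto coarse-grain bands and translated into named
    morphomigrational behaviours (lateral and perpendicular displacement,
    lateral U-turn, stretching, rear retraction, rounded chaotic movement)
    by a rule engine. Includes a synthetic cell-motion generator with
    analytic ground truth for validation, per-track summaries, and a
    command-line interface for end-to-end analysis of mask stacks.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    EBImage,
    png,
    stats,
    tibble,
    tiff,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
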