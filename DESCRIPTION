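Package: tapscore
Title: Tumor Area Positivity (TAP) Scoring of PD-L1 Immunohistochemistry on Annotated Slides
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes the Tumor Area Positivity (TAP) score for PD-L1
    immunohistochemistry from annotated digital-slide data (cell tables plus
    region polygons in micrometers), alongside the cell-counting Combined
    Positive Score (CPS) on the same data model. Builds the tumor-area
    denominator geometry with the 10x-field merging rule, mucin/lumen and
    lymphovascular inclusions, necrosis and artifact exclusions, and
    lymph-node leading-edge rules; applies the cell-level positivity and
    eligibility rules for tumor cells and tumor-associated immune cells; and
    provides the reader-agreement statistics used to validate visual scoring
    methods (average positive/negative agreement, overall/positive/negative
    percent agreement) with Wilson score and cluster-bootstrap confidence
    intervals. A synthetic slide and reader-panel generator with analytic
    ground truth, plus a rasterized brute-force scoring oracle, make the
    full precision-study design reproducible at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    polyclip,
    EBImage,
    jsonlite,
    readr,
    tibble,
    dplyr,
    stats,
    utils,
    grDevices,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
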