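Package: vesselmorph
Title: Automated Retinal Vascular Morphometry from Segmented Vessel Masks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Extracts centerline graphs from binary artery and vein
    segmentation masks of fundus photographs, assigns Strahler orders,
    classifies vessel junctions into branching points, bifurcation points
    and crossings, and measures vascular morphometry (main angle, branching
    angle, branching coefficient, bifurcation edge angle and coefficient)
    inside an optic-disc-centered annulus. Includes a parametric synthetic
    vasculature generator with exact ground truth for validation, cohort
    simulation from group-level summary statistics, and group-comparison
    statistics (descriptives, one-way ANOVA, pairwise mean differences).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    png,
    tiff,
    igraph,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    emmeans,
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
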