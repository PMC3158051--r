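Package: chromterr
Title: Morphometry and Pairing Topology of 3D Chromosome Paint Territories
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantitative scoring of whole-chromosome paint FISH territories
    in 3D image stacks of C. elegans germ lines: territory segmentation from
    multi-channel voxel data, centerline extraction and shape morphometry
    (width, length, slenderness ratio, painted-segment counts), edge-to-edge
    proximity classification between territories, per-coordinate homolog
    association profiles and pairing-configuration taxonomy, gonad zone
    assignment, and the associated nonparametric category statistics. Includes
    a ground-truthed synthetic 3D image generator emulating compact ovoid and
    longitudinally extended territories, beads-on-a-string intensity
    modulation, homolog pairing configurations and row-organized gonads, so
    every scoring step can be validated against known geometry.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    jsonlite,
    Rcpp,
    stats,
    tiff,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
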