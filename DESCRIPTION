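Package: ependyflow
Title: Planar Polarity and Ciliary Flow Analysis for Multiciliated Epithelia
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies planar cell polarity of multiciliated ependymal
    cells from labeled cell-boundary images and basal-body point sets
    (translational distance, basal-body patch angle, Feret's angle and
    longest diameter, rotational-polarity vectors), analyses near-wall
    flow direction from fluorescent-microsphere videos (particle
    detection, nearest-neighbour track linking, circular direction
    statistics with Watson's two-sample U2 homogeneity test and the
    Rayleigh uniformity test), and computes cohort allele-frequency
    statistics (minor allele frequency, 2x2 chi-square with Yates
    continuity correction). A synthetic-epithelium and flow-field
    generator with full ground truth makes every stage of the pipeline
    verifiable without microscopy data.
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
    tiff,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
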