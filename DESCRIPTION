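Package: ribbonquant
Title: Quantification of Gene Expression Along Curved Epithelial Leading
    Edges and Tissue-Closure Kinematics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for measuring fluorescence in situ hybridisation signal
    along the curved leading edge of the Drosophila embryo during dorsal
    closure: spline-based midline fitting and ribbon straightening,
    amnioserosa background correction, segment splitting with length
    normalisation into per-cell bins, anterior/posterior compartment
    statistics and multi-embryo pooling.  Also provides dorsal-closure
    kinematics from annotated time-lapse contours (seam fraction, height
    profiles, stage-binned closure speeds, zipping-zone and closure-delay
    distances), a synthetic embryo and closure-series generator with known
    ground truth, and small screen statistics (fold-change filtering,
    false-discovery expectations, and a Monte-Carlo one-way equal-means
    test).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    pracma,
    stats,
    tiff,
    utils
Suggests:
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
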