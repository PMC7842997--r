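Package: hidimsel
Title: Hybrid Filter-Wrapper Gene Selection and Classification for
    High-Dimensional Expression Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Gene selection and binary classification for high-dimensional
    expression matrices (microarray CSV exports and GEO SOFT GDS files).
    Implements a three-stage pipeline: curation that removes genes whose
    class-wise mean or median ratio lies in a near-unity band, 10-fold
    t-test and Wilcoxon rank-sum filter ranking aggregated into a global
    weight, and a geometric binary particle swarm wrapper driven by the
    cross-validated accuracy of a polynomial-kernel support vector
    machine.  Reports accuracy and precision of the final gene subset and
    exports selected genes, score tables and heatmap matrices.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    e1071,
    grDevices,
    stats,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    optparse,
    pheatmap,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
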