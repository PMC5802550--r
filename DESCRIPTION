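Package: orgcyto
Title: Computational Anatomy and Coexpression-Network Analysis of Cerebral Organoid Sections
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative analysis of cerebral-organoid histology and progenitor
    transcriptomes. Implements minimum-spanning-tree dispersion statistics for
    proliferating-cell point patterns, interneuron length and orientation
    morphometry relative to a cortical surface curve, region-of-interest
    fluorescence intensity and colocalization quantification, thresholded
    gene-coexpression network construction and deconstruction metrics, and the
    accompanying statistical tests (Welch and pooled t-tests, one- and two-way
    ANOVA with Tukey post hoc comparisons, two-sample Kolmogorov-Smirnov).
    Ships a synthetic-data generator that emulates rosette sections, oriented
    interneurons, and replicate expression tables with planted correlated gene
    modules, so every stage of the pipeline can be exercised and validated
    without external imaging or sequencing data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    car,
    dplyr,
    EBImage,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    png,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    mgcv
Config/testthat/edition: 3
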