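Package: crossScreen
Title: Cross-Species Whole-Genome siRNA Screen Analysis for CHO Cells
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for cross-species RNA-interference screens in
    suspension CHO cells: per-plate normalization of fluorescence and
    luminescence readouts to negative-control medians, common-seed based
    off-target correction, mapping of siRNA guide strands to one or more
    transcriptomes with at most one mismatch in reverse-complement
    orientation, grouping of genes across transcriptomes by identical
    targeting siRNA sets, robust median + 3*MAD hit calling, and
    batch-culture characterization (cell volume, viable cell volume,
    cumulative cell days, maximum-correlation-window growth rates and
    specific productivities, and 2^-ddCt knockdown quantification). A
    synthetic-data generator with known ground truth supports end-to-end
    recovery testing of every stage.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    Biostrings,
    multcomp,
    jsonlite,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
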