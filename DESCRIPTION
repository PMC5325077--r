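Package: slicepattern
Title: Spatial Expression Pattern Analysis for Cryosliced Embryos
Version: 0.1.0
Authors@R: person("Slicepattern", "Developers", email = "slicepattern@example.org",
    role = c("aut", "cre"))
Description: Analysis of spatial gene-expression patterns measured by
    cryosectioning embryos along the anteroposterior axis and sequencing
    RNA from each slice.  Per-gene slice profiles are compared between
    genotypes with the exact one-dimensional Earth Mover's Distance
    (Wasserstein-1), patterns are classified as uniform or patterned
    using EMD to a uniform distribution, a differential-response
    statistic (delta-D) quantifies whether two mutants perturb a gene in
    the same way, and transcription-factor ChIP binding near
    transcription start sites is tested for enrichment among changing
    genes.  Includes a synthetic sliced-embryo cohort generator with
    known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    data.table,
    jsonlite,
    yaml,
    IRanges,
    GenomicRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    withr,
    pheatmap
Config/testthat/edition: 3
RoxygenNote: 7.3.3
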