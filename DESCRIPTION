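Package: refplace
Title: Individual Ancestry Placement in a Fixed PCA Reference Space
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Estimates individual genetic ancestry by projecting genotyped or
    low-coverage-sequenced samples, one at a time, into a fixed principal
    component reference space via projection Procrustes analysis. Each study
    sample is combined with the N reference individuals on their shared
    variants, a joint PCA of the N+1 individuals is computed, and the fitted
    Procrustes transform places the sample into the reference coordinate
    system without the shrinkage that affects naive loading-based projection.
    Per-sample diagnostics include the Procrustes similarity t, a reference
    panel appropriateness Z score based on a genetic-variance statistic, and
    k-nearest-neighbour ancestry composition. A Balding-Nichols simulator
    generates structured reference panels, study cohorts (including admixed
    and out-of-panel individuals) and sequencing read data so the full
    pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    rlang,
    stats,
    tibble,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
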