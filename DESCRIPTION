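Package: koaev
Title: Serum Extracellular-Vesicle Tetraspanin Profiling and Small-Cohort
    Classification in Knee Osteoarthritis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for multimodal knee-osteoarthritis cohorts
    combining serum extracellular-vesicle (EV) tetraspanin subpopulation
    accounting with cartilage, functional, and pain variables. Provides
    single-EV size gating and co-localization profiling per capture marker,
    per-millilitre concentration accounting, rank-based and covariate-adjusted
    group statistics with Benjamini-Hochberg false-discovery-rate control,
    correlation-based variable-group identification, subject-level principal
    component analysis and Ward hierarchical clustering, and a group-sampling
    pseudo-subject data-enrichment procedure with random-forest classification
    and mean-decrease-in-impurity feature importance. A seeded block-covariance
    cohort simulator and single-particle EV table generator make every stage
    testable without access to patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    jsonlite,
    mclust,
    ranger,
    stats,
    tools,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
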