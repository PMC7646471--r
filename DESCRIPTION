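Package: apohot
Title: APOBEC-Associated Hotspot Mutations: Discovery and Driver/Passenger
    Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for discovering APOBEC-associated somatic hotspot
    mutations in tumour cohorts and classifying them as drivers or passengers.
    Implements head/tail recurrence thresholding, 96-channel mutational
    catalogues with fixed-profile signature refitting (multinomial EM),
    carrier-association testing against the APOBEC signature, replication
    fork directionality strand asymmetry, a nearest-neighbour DNA hairpin
    minimum-free-energy folder with normalised loop stability scoring,
    housekeeping-normalised expression percentile ranks, an iterative
    similarity-based driver/passenger classifier with exhaustive permutation
    FDR, a mutability-adjusted selection surrogate with exact one-dimensional
    two-cluster splitting, and transcription-factor regulon construction,
    validation and single-sample activity scoring.  Includes a fully seeded
    synthetic data generator emulating every input the pipeline consumes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    jsonlite,
    lme4,
    DESeq2,
    S4Vectors
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
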