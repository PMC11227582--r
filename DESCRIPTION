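Package: striatools
Title: Striatal Acetylcholine Photometry, Vesicle Co-Localization and
    Food-Addiction Criterion Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A tested pipeline for the desk-scale analyses used to characterize
    cholinergic interneuron signaling in the dorsal striatum: fiber-photometry
    dF/F preprocessing with isosbestic-control subtraction and rolling-median /
    MAD transient detection, nearest-neighbor-distance co-localization of
    two-color STED spot fields with threshold-based co-expression
    classification, vesicular-uptake synergy arithmetic, percentile-based
    food-addiction criterion classification, cohort allele-frequency
    arithmetic, and seeded synthetic-data generators with known ground truth
    for parameter-recovery testing.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    rlang,
    jsonlite,
    minpack.lm,
    MASS,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
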