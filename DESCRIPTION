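Package: lumispan
Title: Survival-Curve Inference and Plate Normalization for Bioluminescent
    C. elegans Toxicology Assays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantitative pipeline for Caenorhabditis elegans
    bioluminescent-biosensor toxicology studies: polynomial logistic
    (quasi-binomial) survival-curve models with overdispersion, median
    lifespan estimation by curve inversion, percentile-bootstrap confidence
    intervals, coverage validation experiments, and 96-well plate
    luminescence normalization (background subtraction, technical-replicate
    aggregation, percent-of-solvent-control). Includes seeded synthetic-data
    generators for lifespan count series and plate assays so the full
    pipeline can be exercised and validated without laboratory data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
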