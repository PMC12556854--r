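Package: g4melt
Title: Prediction of DNA G-Quadruplex Melting Temperatures from Sequence
    and Ionic Conditions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Multi-input neural-network regression of DNA G-quadruplex
    melting temperature (Tm) from primary sequence, monovalent-cation
    concentrations (K+, Na+, pooled Li+/NH4+) and pH. Provides dataset
    reading, validation and deduplication; one-hot and k-mer feature
    encoding with min-max condition scaling; a four-branch regressor
    (convolutional, bidirectional-LSTM, and dense branches) trained with
    the Nadam optimizer; repeated k-fold cross-validation with error
    stratification; ensemble prediction with standard errors; G4 motif
    stability scans across ionic conditions; genome-scale stability
    profiling of experimentally validated G4 tables; and a synthetic-data
    generator with a documented toy thermodynamic oracle for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    Rcpp,
    stats,
    utils,
    tools,
    jsonlite,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    car
Suggests:
    testthat (>= 3.0.0),
    e1071,
    xgboost
Config/testthat/edition: 3
LinkingTo:
    Rcpp,
    RcppArmadillo
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
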