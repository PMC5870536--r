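Package: ppap
Title: Reaction-Type Prediction for Plant Type III Polyketide Synthases
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts the reaction type of plant type III polyketide synthases
    (R-4-A, R-4-C, R-2-X or other) from protein sequences. Combines profile
    scores built from short, structurally informative sequence segments
    ("Areas") with correlation scores derived from mutual-information-based
    correlated mutation analysis (MIp with average product correction), and
    classifies queries with a cascade of binary linear discriminant
    classifiers. Includes leave-one-out and repeated random sub-sampling
    validation harnesses, a PCA report on score vectors, and a synthetic
    family generator with planted segment motifs and covarying residue pairs
    so the whole pipeline can be exercised without external sequence
    databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo: Rcpp
Suggests:
    MASS,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
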