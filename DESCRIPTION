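Package: coalunits
Title: Conservation-Unit Delimitation from Microsatellite and Chloroplast
    Data via Coalescent Simulation and Approximate Bayesian Computation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for small-scale conservation genetics of long-lived
    plants: diversity and differentiation statistics for diploid
    microsatellite genotypes (Na, Ne, Ho, He, FIS, AMOVA with permutation
    tests, standardized F'ST, the RST vs. permuted-RST test, PCoA),
    chloroplast-sequence summaries and neutrality tests (haplotype and
    nucleotide diversity, Tajima's D, Fu and Li's D* and F*, phiST and
    phi'ST), an event-driven structured coalescent simulator with
    generalized stepwise microsatellite mutation, approximate Bayesian
    computation with random-forest model choice and regression-adjusted
    posteriors, and a rule-based decision stage that delimits
    evolutionarily significant units and management units.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    ape,
    jsonlite,
    nnet,
    randomForest,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
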