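Package: glycosim
Title: Individual-Based Eco-Evolutionary Simulation of Core Yeast Glycolysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulates populations of yeast-like cells carrying a simplified
    glycolysis pathway (upper glycolysis, lower glycolysis, a general ATPase
    demand reaction and vacuolar phosphate transport) whose maximal rate
    constants evolve by mutation and selection. Each cell integrates kinetic
    ordinary differential equations for FBP, ATP and inorganic phosphate
    together with volume growth and a health variable, using an adaptive
    Dormand-Prince 5(4) method with a non-negativity projection. Populations
    grow, divide, mutate, die and wash out of either a chemostat (cells
    deplete shared glucose) or an imposed-glucose chamber with no competition
    for glucose. Includes balancedness statistics that classify balanced
    versus imbalanced glycolytic strategies, genotypic balancedness scans,
    two-genotype competition experiments, and configuration/preset handling
    for reproducible runs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    pracma,
    stats,
    utils,
    yaml,
    jsonlite
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    optparse
Config/testthat/edition: 3
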