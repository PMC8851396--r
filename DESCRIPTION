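Package: phenometab
Title: Phenomics-Metabolomics Integration for Biostimulant Characterisation
Version: 0.1.0
Authors@R:
    person("Plant", "Phenomics Lab", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for characterising the mode of action of plant
    biostimulants from paired high-throughput phenotyping and untargeted
    metabolomics experiments. Derives morpho-physiological traits (digital
    biomass, relative growth rate, chlorophyll fluorescence parameters,
    canopy temperature depression, water-use efficiency) from per-plant
    imaging exports, scores substances with the Plant Biostimulant
    Characterisation (PBC) index, discriminates treatments by Ward
    hierarchical clustering and OPLS-DA with VIP ranking, CV-ANOVA and
    permutation validation, detects differential metabolites by combined
    ANOVA/fold-change volcano filtering, ranks traits by random-forest
    permutation importance, and quantifies phenome-metabolome concordance
    by co-inertia analysis and the RV coefficient. A synthetic-data module
    generates coupled phenotyping and metabolite tables with known ground
    truth for pipeline validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    graphics,
    ape
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
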