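Package: rhizoflux
Title: Constraint-Based Modelling and Transcriptome-Guided Contextualization
    of Rhizobial Metabolism
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Genome-scale metabolic modelling toolkit for characterizing
    bacterial lifestyles, built around the workflows used to study
    Rhizobium-legume symbioses. Provides flux balance analysis with a
    taxicab-norm (parsimonious) secondary objective, flux variability
    analysis (plain and cycle-free), MOMA-based gene essentiality,
    hit-and-run flux sampling, construction of in-silico nutrient
    environments from metabolite lists, transcriptome-guided extraction of
    context-specific models with task protection and an objective-fraction
    sweep, reporter-metabolite analysis over the network topology, and the
    validation statistics (confusion metrics, measured-flux versus FVA
    comparison, amino-acid enrichment) used to benchmark such models.
    Includes generators for synthetic mass-balanced toy models, expression
    profiles with planted active subnetworks, and brute-force essentiality
    labels, so the whole pipeline is exercisable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    Rcpp,
    jsonlite,
    xml2,
    quadprog,
    Biostrings
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
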