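Package: mangroveED
Title: Phylogenetic Diversity, Community Structure and Extinction Risk in
    Mangrove Floras
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing the phylogenetic structure of threat in
    coastal plant assemblages, built around the mangrove biome. Computes
    per-species evolutionary distinctiveness (fair proportion) and species
    ages (terminal branch lengths) from a dated phylogeny; standardized
    community phylogenetic indices (NRI/NTI) against a tip-pool null model;
    Blomberg's K with permutation tests; phylogenetic generalized least
    squares with maximum-likelihood estimation of Pagel's lambda;
    IUCN Red List category to extinction-probability transforms and
    Yates-corrected chi-squared tests of use-decline association; equal-area
    (Behrmann) gridding of species ranges into richness, decline and
    phylodiversity layers with layer correlations; a synthetic-study
    generator emulating the statistical structure of the real data; and a
    config-driven pipeline with a small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    nlme,
    withr
Config/testthat/edition: 3
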