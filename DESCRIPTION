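Package: gradiv
Title: Taxonomic, Phylogenetic and Functional Diversity Along Environmental Gradients
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Community phylogenetics toolkit for elevational-gradient studies of
    woody plant assemblages. Computes phylogenetic signal of functional traits
    (Blomberg's K and Pagel's lambda with tip-randomization significance),
    builds a functional trait dendrogram (log-standardized traits, PCA,
    Euclidean distance, UPGMA), quantifies taxonomic, phylogenetic and
    functional alpha and beta diversity with abundance-weighted mean pairwise
    distance, a tip-shuffle null model and the net relatedness index (NRI),
    and attributes diversity patterns to climatic, habitat and geographic
    drivers via simple OLS, simple Mantel tests, all-subsets AICc model
    averaging with Akaike-weight variable importance, variation partitioning
    and multiple regression on distance matrices (MRM). Includes a synthetic
    data generator (Yule trees, lambda-structured Brownian traits,
    filtering/competition/neutral community assembly along an elevation
    gradient) with known ground truth for end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    picante,
    phytools,
    vegan,
    geosphere,
    jsonlite,
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
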