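Package: MarkerDiversity
Title: Genetic Diversity Analysis from Dominant Markers, Field Trials and
    Phytochemical Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Integrated genetic-diversity analysis for germplasm panels
    characterised with dominant (binary band) molecular markers,
    randomized-complete-block field trials and compound-concentration
    profiles. Provides marker informativeness indices (polymorphic
    information content, resolving power, effective multiplex ratio,
    marker index, effective marker index), RCBD variance-component
    estimation with genotypic and phenotypic coefficients of variation,
    broad-sense heritability and genetic advance, Jaccard and Euclidean
    distance construction with distance-matrix fusion, UPGMA and
    Lance-Williams hierarchical clustering with Newick export and
    cophenetic comparison, silhouette-guided k-means, PCA, distance-based
    AMOVA with Phi-statistics and permutation tests, principal coordinate
    analysis, the Mantel test, Evanno delta-K post-processing of admixture
    log-likelihoods, and seeded simulators that generate marker, trait and
    chemotype data with known structure for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    ape,
    cluster,
    mclust,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
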