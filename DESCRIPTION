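Package: formulanet
Title: Jaccard Clustering and Herb-Indication Network Mining of Herbal
    Prescription Corpora
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for quantitative rule mining of multi-herb prescription
    corpora from the East Asian traditional medicine literature. Prescriptions
    are represented as binary herb and indication presence/absence vectors;
    pairwise dissimilarity uses the Jaccard distance on herb sets. The package
    provides agglomerative hierarchical clustering with dendrogram export,
    k-means partitioning on a classical multidimensional-scaling embedding of
    the Jaccard distance matrix with fully seeded initialization, cluster
    validity assessment via the silhouette index and a zero-overlap
    misclassification statistic (the fraction of prescription pairs sharing no
    herb that are nonetheless co-clustered), sensitivity sweeps over the number
    of clusters and over random seeds with stable-core extraction, bipartite
    herb-indication co-occurrence networks and cluster-specific subnetworks
    with common-major-node comparison, and a planted-partition synthetic corpus
    generator for end-to-end parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    ape,
    igraph,
    jsonlite,
    yaml,
    digest
Suggests:
    testthat (>= 3.0.0),
    cluster,
    mclust,
    vegan,
    optparse,
    withr
Config/testthat/edition: 3
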