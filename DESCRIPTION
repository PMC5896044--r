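Package: ttclust
Title: Two-Tiered Unsupervised Drug Clustering for Repositioning
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Integrates heterogeneous binary drug profiles (chemical
    fingerprints, disease indications, genes, target proteins, side effects)
    by a two-tiered unsupervised clustering scheme: each profile view is
    clustered with a Growing Self-Organizing Map, per-view drug-drug relation
    matrices derived from cluster co-membership are averaged into a single
    similarity graph, and the graph is re-clustered with Markov Clustering,
    MCODE, ClusterONE or a second GSOM. Clusters are labeled with their
    majority second-level ATC therapeutic class and a confidence measure,
    from which drug repositioning candidates are inferred. Includes internal
    (Silhouette) and external (normalized and standardized mutual
    information) cluster evaluation, baseline integration strategies
    (feature concatenation and averaged Jaccard similarity), and a synthetic
    multi-view profile generator with planted drug groups for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    grDevices,
    igraph,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    cluster,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
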