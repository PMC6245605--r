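Package: shapeclust
Title: Shape-Based Clustering of Protein 3D Structures
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discovers groups of structurally similar protein 3D models from
    their atom point clouds. Pairs of models are superposed with a simplified
    TM-align procedure (Kabsch rotations iterated with dynamic programming on a
    TM-score matrix); local and global 3D shape descriptors (fast point feature
    histograms, 3D shape context, radius-based surface descriptors, viewpoint
    feature histograms) are extracted from the aligned point clouds; pairwise
    descriptor-space RMSD matrices are built, optionally fused with equal or
    silhouette-based weights, and clustered with k-medoids, average-linkage
    agglomerative clustering or DBSCAN, selecting the number of clusters by the
    average silhouette width. Clusterings are evaluated against ground-truth
    labels with the Rand index. Includes a generator of synthetic families of
    protein-like models so the whole pipeline can be exercised without external
    data, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    bio3d,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    cluster,
    mclust,
    optparse,
    jsonlite
Config/testthat/edition: 3
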