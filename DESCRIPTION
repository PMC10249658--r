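Package: voxmg
Title: Voxel-Based Deep Learning Prediction of Magnesium Ion Binding Sites
    in RNA Structures
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Locates Mg2+ ions in RNA three-dimensional structures. The
    neighbourhood of every nucleotide is voxelized into a two-channel 3D
    image (volume occupancy and partial charge), a residual 3D regression
    convolutional network predicts a per-voxel ion probability grid, and
    overlapping grids are assembled, clustered (DBSCAN plus weighted
    k-means) and ranked into discrete binding-site predictions. Includes
    evaluation against experimentally observed ions (TPR/PPV at a distance
    cutoff), input-gradient saliency analysis projected back onto RNA
    atoms, geometric classification of inner-sphere coordination motifs
    (10-/16-member rings, phosphate pyramid, magnesium clamp and related),
    and a seeded generator of synthetic RNA fixtures with planted
    octahedral Mg2+ sites so that training and testing run without
    external data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    data.table,
    igraph,
    jsonlite,
    optparse,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
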