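Package: somseg
Title: Unsupervised Brain MRI Tissue Segmentation with 3D Texture Descriptors, Self-Organizing Maps and Fuzzy Clustering
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Unsupervised segmentation of skull-stripped T1-weighted brain MRI
    volumes into cerebrospinal fluid, gray matter and white matter. Every brain
    voxel is described by a 23-dimensional statistical descriptor combining
    Haralick texture features from 13-direction three-dimensional gray-level
    co-occurrence matrices, first-order window statistics, local-histogram
    moments and a global intensity probability. The descriptors are vector
    quantized by a self-organizing map whose prototypes are grouped into tissue
    clusters with fuzzy c-means; voxels inherit graded memberships through
    their best matching unit, and a membership-difference threshold yields
    multi-label assignments for voxels affected by the partial volume effect.
    Includes a genetic-algorithm wrapper for feature-subset selection scored by
    the Jaccard overlap against reference label maps, a three-tissue synthetic
    phantom generator, per-tissue Jaccard evaluation, and minimal NIfTI-1
    input/output.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
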