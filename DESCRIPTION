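Package: facegauge
Title: Batch Registration and Mutual Similarity of 3D Facial Surface Scans
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Nearly-linear-time batch (N:N) registration and mutual
    similarity measurement of open triangular shell meshes such as
    stereophotogrammetric facial scans. Implements one-directional
    iterative closest point (ICP) registration embedded in a generalized
    Procrustes loop that transmutes a template mesh into an average face,
    automatic cropping of non-overlapping surface regions via boundary-edge
    detection, random / uniform-grid / curvature-based vertex sub-sampling,
    a modified Hausdorff surface distance, and indirect gauge-based
    pairwise distance measurement through the average face. Includes
    readers and writers for OBJ, PLY and STL meshes and a synthetic
    shell-population generator for validation.
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
    yaml,
    optparse,
    pracma
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
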