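Package: cortimorph
Title: Surface-Based Cortical Morphometry on Pial and White Surface Pairs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for surface-based morphometry of the cerebral cortex from
    triangulated pial and white surface pairs. Computes per-vertex principal,
    Gaussian and mean curvature, the Koenderink shape index with a nine-way
    and three-way shape classification, bidirectional closest-point cortical
    thickness, an alpha (exposed) surface built by morphological closing of a
    signed distance field, and per-vertex sulcal depth. Reduces vertex fields
    to subject-level metrics (surface areas, gyrification index, enclosed
    volume, folding amplitude, convex/concave thickness ratio) and provides
    cohort statistics: shape-binned thickness distributions, effect-size
    contrasts, aging trends, and allometric log-log/semilog scaling fits with
    isometry comparison. Includes seed-deterministic synthetic folded phantom
    generators with ground truth so every stage can be validated without
    external data, and readers/writers for FreeSurfer binary, GIFTI, PLY and
    OFF surfaces and FreeSurfer curv / CSV vertex maps.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    Matrix,
    methods,
    xml2,
    jsonlite,
    pracma,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
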