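Package: SphereScan
Title: Identification of 3D Mutational Hotspots on Protein Structures
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Identifies statistically significant three-dimensional mutational
    hotspots on protein structures. Somatic missense mutations are mapped onto
    residue alpha-carbon coordinates and the one, two or three non-overlapping
    spheres covering the most mutation occurrences are found over a grid of
    radii by a best-first lattice search with a brute-force oracle for
    verification. Observed maximal coverage is normalized against a Monte-Carlo
    null in which mutations are placed uniformly over residues, yielding a
    single simulation p-value per structure, with a rough false-discovery-rate
    threshold applied across structures. Includes a synthetic structure and
    mutation-table generator so the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    bio3d,
    Biostrings,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
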