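Package: metabconn
Title: Interregional Metabolic Connectivity Networks from Small-Animal FDG-PET
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Builds group-level metabolic connectivity networks from regional
    FDG-PET uptake. Per-subject volume-of-interest (VOI) uptake is normalized
    to a standard uptake value ratio (SUVR) against a reference region
    (bilateral medulla by default), inter-subject Pearson correlation matrices
    are computed per group and Fisher r-to-z transformed, and every region
    pair is tested for a between-group connectivity difference with a
    group-label permutation test, classifying edges as increased or decreased
    at tiered significance thresholds. Includes a seeded synthetic-cohort
    generator with controllable interregional correlation structure and
    injectable edge-level group differences for power and calibration studies.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    MASS,
    stats,
    utils
Suggests:
    igraph,
    yaml,
    Matrix,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
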