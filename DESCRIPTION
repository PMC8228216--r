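Package: spermform
Title: Sperm Form-Function Analysis: CASA Kinematics, Motility QC,
    Morphology Statistics and Haplotype Networks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for analysing the relationship between sperm morphology
    and swimming performance in island bird populations. Computes
    computer-assisted sperm analysis (CASA) track kinematics (curvilinear,
    straight-line and average-path velocity, straightness and linearity),
    applies an object/motility/speed-eligibility quality-control cascade,
    derives sperm morphology summaries with small-sample-corrected
    coefficients of variation, fits within-event-centred mixed models of
    swimming speed and motile proportion with interaction selection, and
    builds minimum spanning networks of mitochondrial haplotypes. Includes
    a synthetic-data generator with known ground truth so the whole
    pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    lme4,
    lmerTest,
    car,
    ape,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
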