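Package: qsar3d
Title: Three-Dimensional QSAR with CoMFA and CoMSIA Molecular Fields
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for three-dimensional quantitative structure-activity
    relationship (3D-QSAR) analysis of aligned small-molecule series:
    common-skeleton rigid alignment (Kabsch superposition), CoMFA
    steric/electrostatic and CoMSIA Gaussian similarity fields sampled on a
    cubic lattice, partial least squares (PLS) regression with leave-one-out
    cross-validation, the Golbraikh-Tropsha external-validation battery with
    Y-randomization, StDev*Coeff contour extraction, and MM/GBSA binding
    free-energy bookkeeping.  A synthetic-data generator with planted
    regional field weights supports end-to-end validation, and the activity
    and binding-energy tables of a 41-compound stilbene-derived series of
    reversible LSD1 inhibitors are embedded as reference fixtures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    methods,
    jsonlite,
    yaml,
    bio3d,
    ChemmineR
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    ChemmineOB,
    mixOmics
Config/testthat/edition: 3
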