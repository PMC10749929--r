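Package: emstitch
Title: Montaging and Elastic 3D Alignment of Serial-Section Multibeam SEM Stacks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale pipeline for assembling serial-section multibeam
    scanning electron microscopy (mSEM) volumes: 2D montaging of hexagonal
    multi-field-of-view (mFOV) tile layouts with normalized cross-correlation
    template matching and a global tile-position least-squares solve,
    two-pass per-beam gradient and brightness correction with a sub-tile
    histogram-shift refinement, masked histogram matching for 3D contrast
    balancing, coarse/rough/fine/ultrafine 3D alignment built on constrained
    2D Procrustes fits, RANSAC, moving-least-squares deformation and
    per-grid-point delta least squares, semi-automated tear healing, and
    blockwise inverse-transform export. Includes a synthetic-fixture
    generator with known planted deformations so every stage can be tested
    end to end without real acquisition data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    igraph,
    png,
    EBImage,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    MASS
Config/testthat/edition: 3
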