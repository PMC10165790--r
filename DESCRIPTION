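Package: BraceMorph
Title: Torso Asymmetry and Brace-Fit Morphometrics from 3D Surface Meshes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Measurement pipeline for computer-aided-design (CAD) brace
    analysis in adolescent idiopathic scoliosis. Computes a torso (or brace)
    asymmetry index by mirroring a surface mesh across its mid-sagittal
    plane, registering the mirror with iterative closest point, trimming to
    equal length and taking the enclosed inter-surface volume as a fraction
    of the torso volume; computes signed torso-to-brace displacement fields
    (pressure and expansion zones), partitions the torso into the twelve
    standard anterior/posterior x left/right x upper/mid/lower segments and
    extracts peak displacements per segment; derives initial in-brace
    correction from Cobb angles and builds Spearman rank-correlation tables
    with strength categories. Includes watertight synthetic torso and brace
    phantom generators and a seeded cohort simulator with known
    feature-to-correction effect structure so the whole pipeline is testable
    without patient scans. Mesh I/O supports STL, PLY and OBJ.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
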