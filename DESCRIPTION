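Package: hexamesh
Title: Tetrahedral-to-Hexahedral Mesh Conversion and Finite-Element
    Preprocessing for Head-Neck Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Preprocessing toolkit for subject-specific head-neck finite
    element models. Converts unstructured tetrahedral volume meshes into
    conformal all-hexahedral meshes (four hexahedra per tetrahedron via
    edge midpoints, face centroids and the element centroid) with a
    140-degree face-corner angle constraint enforced by geometry-preserving
    constrained smoothing. Includes element quality metrics (scaled
    Jacobian, aspect ratio, skewness, warping, maximum corner angle) with
    threshold-based mesh reports, evaluators for the constitutive models
    used in head-neck tissue simulation (linear viscoelastic, polynomial
    hyperelastic, hyper-viscoelastic with Prony series, Hill-type muscle,
    linear ligament springs, strain-based element erosion), cervical
    vertebral morphometry (vertebral body dimensions, Frobin dimensionless
    disk height, PCA reorientation, surface thickness, enclosed volume) and
    validation-curve statistics, plus deterministic synthetic fixture
    generators. Reads and writes VTK unstructured (legacy and XML), STL
    (ASCII and binary), Abaqus-style .inp and LS-DYNA keyword formats.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    yaml,
    xml2
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
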