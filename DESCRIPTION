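Package: splintforge
Title: Scriptable Design of Orthognathic Dental Splints from Triangle Meshes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Computer-aided design of occlusal surgical splints for
    orthognathic surgery as a scriptable pipeline: an initial splint solid
    is built from an ordered plan of landmark lines via spline resampling
    and ruled-surface assembly; the maxilla and mandible meshes are
    subtracted with a triangle-mesh Boolean engine based on
    intersection-curve splitting and signed-distance classification; and
    undercuts are removed by reconstructing the swept silhouette of the
    dentition along a removal direction (contour slicing, cumulative
    accumulation, voxelization, morphological closing and isosurface
    extraction) and subtracting it. Includes binary and ASCII STL input
    and output, watertightness and volume diagnostics, surface-distance
    validation metrics, and deterministic synthetic phantoms (cone
    frusta and a toy dental arch) for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
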