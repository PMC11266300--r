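Package: ossm
Title: Statistical Shape Models of Long Bones from Volumes and Meshes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: An end-to-end statistical shape modelling pipeline for long
    bones, built for canine hind-limb morphometry. Provides threshold
    segmentation and morphological closing of CT-like volumes, iso-surface
    extraction, uniform isotropic remeshing, sphere-fit anatomical
    coordinate frames, partial-bone cuts, nearest-neighbour dense
    correspondence against a median template, and PCA point-distribution
    models with variance-explained tables and mode-shape synthesis at
    plus/minus three standard deviations. Includes a synthetic bone
    population generator with known latent factors (scale, varus/valgus,
    procurvation, torsion, condylar width) so that every pipeline stage is
    testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    jsonlite,
    igraph,
    RNifti
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
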