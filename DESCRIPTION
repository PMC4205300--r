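Package: landcorr
Title: Landmark Annotation Variability and Dense Point Correspondence for 3D Facial Surfaces
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying operator variability of manually annotated 3D
    facial landmarks and for building dense point correspondences from sparse
    landmark sets. Implements per-landmark error summaries and a balanced
    mixed-model (expected-mean-squares, MIVQUE-equivalent) variance-component
    decomposition of repeated multi-operator annotations; volumetric thin-plate
    spline warping; curvature-guided Markov-random-field refinement of
    template-to-target surface correspondence; point-distribution models with
    generalized Procrustes alignment, compactness, and a coupled leave-one-out
    cross-validation of operator-specific models; and evaluation of sparse
    landmark selections by the dense mean point variance of the resulting
    correspondences. A synthetic-face module generates template and population
    meshes with known true landmarks and simulates repeated annotations, so the
    whole pipeline can be exercised without access to real facial scans.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
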