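Package: vlconn
Title: Virtual Ventriculostomy Lesions in Structural Connectomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates frontal ventriculostomy (Kocher-Monro trajectory)
    instrument passage through whole-brain tractograms and quantifies the
    resulting group-level structural connectome alterations. Provides a
    synthetic tractogram cohort generator, exact cylinder-polyline
    transection geometry, track-weighted fractional anisotropy connectome
    construction with rank-based Gaussian resampling, global graph indices
    and nodal strength, and a three-stage inference battery: permutation
    tests on global indices, gated two-sample t tests with false discovery
    rate control on nodal strength, and the network-based statistic with
    component-level family-wise error control.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    RNifti,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
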