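Package: sparsevda
Title: Sparse Vertex Discriminant Analysis with Distance-to-Set Penalties
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Multiclass linear and kernel classification by vertex discriminant
    analysis (VDA) with an epsilon-insensitive squared loss. Model fitting uses
    majorization-minimization with distance-to-set penalties that enforce exact
    l0-type sparsity on rows, columns, or entries of the coefficient matrix, or
    shrinkage onto l1 balls. Includes projection operators for the six
    constraint sets, an annealed proximal distance solver with thin-SVD direct
    updates and exact-step steepest descent, radial-basis kernel VDA with
    avatar (support instance) selection, a nested cross-validation pipeline for
    tuning the insensitivity radius, kernel scale, and model size, repeated
    cross-validation stability reports, and synthetic-data generators with
    Toeplitz Gaussian designs for benchmarking support recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
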