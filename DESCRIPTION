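Package: abstractnav
Title: Learning Stages and Destination Representations in Abstract Navigation Tasks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates navigation through discrete multidimensional abstract
    feature spaces (grid worlds with six values per dimension), estimates a
    per-path learning level with a feedforward phase classifier trained on
    response-accuracy/response-time step matrices, splits paths into
    exploration and exploitation stages by one-dimensional 2-means
    clustering, runs the associated linear mixed-effect models and auxiliary
    tests, and performs a searchlight representational similarity analysis
    of destination coding on volumetric pattern-estimate maps with
    threshold-free cluster enhancement and sign-flip permutation
    family-wise-error inference. Includes synthetic-data generators for both
    behavior and voxel patterns so every stage of the pipeline can be
    validated by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    lme4,
    lmerTest,
    RNifti,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
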