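Package: kronmda
Title: miRNA-Disease Association Prediction by Symmetric NMF and
    Kronecker Regularized Least Squares
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts candidate miRNA-disease associations from a known
    association list and a disease hierarchy.  Disease similarity is built
    from DAG-based semantic similarity and Gaussian interaction-profile
    kernels; miRNA similarity from functional similarity (group-max over
    associated diseases) and interaction-profile kernels.  The integrated
    similarities are denoised by symmetric non-negative matrix
    factorization and all disease-miRNA pairs are scored in closed form by
    a Kronecker-product regularized least-squares solver.  Includes global
    and local leave-one-out cross-validation, repeated k-fold
    cross-validation, and a planted block-model generator of synthetic
    benchmarks.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
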