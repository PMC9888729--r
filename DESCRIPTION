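Package: fstree
Title: Joint Inference of Coancestry Coefficients and Population Trees
    from Allele Counts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Method-of-moments estimation of FST-style coancestry
    parameters for populations and/or unrelated diploid individuals,
    jointly with a rooted population tree whose branch lengths are drift
    parameters.  Implements the pairwise Hudson-type ratio-of-sums
    estimator, a logarithmic least-squares tree-fitting algorithm solved
    by non-negative least squares (hierarchical clustering plus a
    tip-relocation improvement phase), generalized within- and
    between-population FST matrices computed from the fitted tree, a
    hierarchical beta-drift simulator, and tools to benchmark estimator
    performance on synthetic scenarios.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    ape,
    jsonlite,
    Rcpp,
    S4Vectors,
    SummarizedExperiment
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pracma,
    phangorn,
    vcfR,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
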