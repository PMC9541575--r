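Package: mvmrpca
Title: Multivariable cis-Mendelian Randomization with Correlated Variants
Version: 1.0.0
Authors@R:
    person("mvmrpca", "Developers", email = "mvmrpca@example.org",
           role = c("aut", "cre"))
Description: Estimators for multivariable Mendelian randomization using
    summarized genetic association data when the instruments are correlated
    variants from a single gene region. Implements the multivariable
    inverse-variance weighted (MV-IVW) estimator via generalized least
    squares, a multivariable limited-information maximum likelihood
    (MV-LIML) estimator that minimizes an Anderson-Rubin-type objective,
    and dimension-reduction variants of both that replace the correlated
    variants by principal components of a weighted variant covariance
    matrix. Also provides greedy p-value-based LD pruning, stepwise
    conditional variant selection from individual-level data, and a
    Monte-Carlo simulation engine for Type-1-error and power studies of
    these methods.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports: stats, utils, tools
Suggests: testthat (>= 3.0.0), jsonlite, withr
Config/testthat/edition: 3
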