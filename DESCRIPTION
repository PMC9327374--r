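Package: mvgreml
Title: Multivariate GREML Estimation of SNP Heritability and Genetic Factor Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Multivariate genomic-relatedness-based restricted maximum likelihood
    (GREML) estimation of SNP-based heritability and genetic correlations across
    many traits, with support for user-specified genetic and environmental factor
    models parameterized as V = C C' with a binary pattern of free loadings.
    Phenotypes and covariates are rotated into the eigenbasis of the genomic
    relationship matrix, where the model covariance is block diagonal and the
    restricted log-likelihood, its gradient and the average-information matrix
    are evaluated in O(N T^2) time per iteration. Estimation uses BFGS with a
    golden-section line search, gradient-descent reinitialization on instability
    and a single average-information fallback step. Includes likelihood-ratio
    tests between nested factor models, delta-method standard errors, GLS fixed
    effects, GCTA-format binary GRM input/output, and a simulator of genotypes
    and multivariate polygenic phenotypes with specified factor structure.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
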