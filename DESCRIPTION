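Package: mixpcm
Title: Mixture Partial Credit Models for Diagnosing Rating-Scale Usage
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Marginal maximum likelihood estimation of partial credit and
    generalized partial credit item response models with latent scale-usage
    classes (mPCM, rmGPCM, mGPCM) via EM with Newton refinement and
    Gauss-Hermite quadrature.  Tools for choosing the number of classes
    (CAIC/BIC/AIC, parametric-bootstrap goodness-of-fit and likelihood-ratio
    difference tests), for diagnosing inappropriate scale usage from
    class-specific thresholds (threshold inversions, avoided categories,
    latent category widths, category characteristic curves, expected category
    frequencies, marginal reliability), and for relating class membership to
    covariates with the bias-adjusted three-step multinomial regression.
    Includes a synthetic-data generator emulating left-skewed 11-category
    satisfaction ratings from a three-class mixture.
License: MIT + file LICENSE
Encoding: UTF-8
LinkingTo:
    Rcpp
Imports:
    Rcpp,
    stats,
    utils,
    pracma,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    nnet
Config/testthat/edition: 3
RoxygenNote: 7.3.3
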