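Package: mrrmrr
Title: Robust Regularized Minimum-Redundancy Maximum-Relevance Variable
    Selection for Two-Group High-Dimensional Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Supervised variable selection for noisy two-group data with
    many more variables than samples. Implements the Minimum Regularized
    Redundancy Maximum Robust Relevance (MRRMRR) criterion: relevance is
    measured by a highly robust correlation coefficient derived from least
    weighted squares (LWS) regression with adaptive, linear, or logistic
    rank weights, and redundancy by a regularized coefficient of multiple
    correlation built on a correlation matrix shrunken toward the identity
    with an analytic intensity. Classical minimum-redundancy
    maximum-relevance baselines (mutual information, Pearson, Spearman,
    Kolmogorov-Smirnov and sign-test measures), a linear discriminant
    analysis leave-one-out cross-validation harness with a gamma grid
    search, and a two-group synthetic data generator with Gaussian,
    contaminated-normal, and Cauchy noise models are included.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    MASS
Config/testthat/edition: 3
RoxygenNote: 7.3.3
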