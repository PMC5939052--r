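Package: exgauss
Title: Ex-Gaussian Modelling of Reaction-Time Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for modelling positively skewed chronometric data with the
    ex-Gaussian (exponentially modified Gaussian) distribution. Provides
    numerically stable density, distribution and quantile functions in both
    the (mu, sigma, tau) and the standardized asymmetry (lambda)
    parameterizations, conversions between parameters and moments, seeded
    random variate generation, three estimation procedures (method of
    moments, least squares on a histogram, and maximum likelihood, the
    latter two by an adaptive steepest descent/ascent), parametric-bootstrap
    Kolmogorov-Smirnov goodness-of-fit testing, principled tail-quantile
    trimming of reaction times, a histogram bin-count sensitivity scan, and
    a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    data.table,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pracma,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
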