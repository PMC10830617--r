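Package: attweights
Title: Screen-Time-Based Attentiveness Weighting for Careless Responding
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Detects and down-weights careless/insufficient-effort responding
    (C/IER) in computer-administered surveys from screen times. Log per-item
    screen times are decomposed by group and scale into Gaussian mixture
    components selected by BIC; the lowest-mean component is labelled as
    C/IER and per-respondent posterior class probabilities yield
    attentiveness weights. The weights, multiplied with sampling weights,
    enter a weighted pseudo-likelihood marginal maximum likelihood fit of a
    multi-group generalized partial credit model. Includes threshold-based
    timing indicators and agreement statistics for validity checks, a
    hierarchical random-intercept Beta regression of C/IER proportions on
    scale characteristics (Bayesian and maximum likelihood), a synthetic
    data generator with known ground truth, and a command-line pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    pracma,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mclust,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
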