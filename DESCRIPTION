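Package: dyadtune
Title: Behaviorally Tuned Neuron Analysis for Dyadic Social Dominance Imaging
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Analysis of single-photon calcium imaging recorded while pairs of
    rodents compete for social dominance in the tube test. Provides a synthetic
    dyad generator with ground-truth planted cells, calcium event detection from
    dF/F traces, Gaussian rate convolution, a mixed discrete-continuous
    Kraskov-type k-nearest-neighbour mutual information estimator with
    circular-shuffle permutation nulls, classification of cells as tuned to the
    imaged animal's own behavior, the partner's behavior, or their conjunction,
    and derived reliability, consistency, event-rate, dominance and population
    activity metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    tools,
    utils,
    Rcpp,
    jsonlite,
    S4Vectors,
    SummarizedExperiment
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
biocViews: Software, TimeCourse, Classification
RoxygenNote: 7.3.3
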