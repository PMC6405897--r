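Package: fragsim
Title: Geometric Fragmentation Effects on Species Abundance and Survival
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation framework for quantifying geometric effects of habitat
    loss and fragmentation per se on species abundance and landscape-scale
    survival. Species distributions are generated as realizations of point
    processes in the unit square (complete spatial randomness, the Thomas
    cluster process, and the Strauss inhibition process sampled by
    Metropolis-Hastings), fragmented landscapes as thresholded fractal
    surfaces from the midpoint displacement algorithm with independently
    controlled habitat amount and Hurst factor, or as Boolean landscapes of
    equal-radius circular fragments. Overlaying the two ("cookie-cutter"
    sampling) yields Monte-Carlo estimates of abundance statistics and
    survival probability, cross-validated against the analytical survival
    probability of the Thomas process on circular fragments obtained from the
    void probability of the cluster-process generating functional.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    igraph,
    ggplot2,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
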