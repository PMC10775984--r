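Package: ratemapr
Title: Firing Rate Map Estimation and Benchmarking for Spatially Tuned Neurons
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for constructing firing rate maps of spatially modulated
    neurons (place, grid and boundary cells) from position tracking and spike
    time data.  Implements six estimators: the smoothed bivariate histogram,
    the averaged shifted histogram, adaptive (Skaggs-McNaughton) smoothing,
    adaptive (dwell-time) binning, the kernel smoothed density estimate ratio,
    and a temporal kernel estimator based on instantaneous firing rate.  Also
    provides a ground-truth simulation suite (open-field random walks, place
    cell probability surfaces, Poisson spike generation), map accuracy scoring
    by mean integrated squared error, multi-objective (Pareto) parameter
    optimization, Ripley's K based firing field size estimation and histogram
    bin-size rules of thumb.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    signal,
    stats,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
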