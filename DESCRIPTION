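Package: irkd
Title: Image-Representation Knowledge Distillation for Wearable Sensor
    Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for studying image-representation-driven knowledge
    distillation on multichannel wearable-sensor time series (human
    activity recognition). Converts raw signal windows into Gramian
    angular fields (GASF/GADF) and persistence images (via a built-in
    Vietoris-Rips persistent-homology backend), trains 1-D and 2-D
    WideResNet teachers with a compiled float32 SGD engine, distills a
    compact 1-D student with single- and multi-teacher temperature-scaled
    losses and annealing initialization, and provides corruption
    robustness, weight-space interpolation, and clustering diagnostics.
    Includes a synthetic generator for class-structured quasi-periodic
    accelerometer-like signals so the full pipeline runs without external
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    ggplot2,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
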