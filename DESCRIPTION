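Package: dybm
Title: Dynamic Boltzmann Machines for Binary Spike Sequences
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Energy-based modelling of multivariate binary spike trains with
    a dynamic Boltzmann machine: finite conduction delays realised as FIFO
    queues, exponentially decaying neural and synaptic eligibility traces,
    and an exact online learning rule with the signature of spike-timing
    dependent plasticity (long-term potentiation and two-component
    long-term depression) under per-parameter AdaGrad step sizes. Supports
    sequence memorisation, cue-based associative retrieval of multiple
    stored sequences, and negative log-likelihood anomaly scoring of
    binary time series, together with text-bitmap fixtures, plain-text
    sequence formats and JSON model checkpoints.
License: MIT
Encoding: UTF-8
Imports: Rcpp, jsonlite, stats, utils, graphics
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
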