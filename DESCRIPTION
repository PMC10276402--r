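Package: slamburst
Title: Time-Resolved Transcriptional Bursting Inference from 4sU-Labelled
    Single-Cell RNA-Seq
Version: 0.1.0
Authors@R:
    person("Robin", "Tarn", email = "rtarn@example.org", role = c("aut", "cre"))
Description: Joint Bayesian inference of transcriptional bursting kinetics
    (burst size, burst frequency, transcript decay rate) from metabolic RNA
    labelling (4sU/SLAM) single-cell RNA-seq data. Implements nested
    likelihood models over per-cell UMI counts and per-read T>C conversion
    counts built on the telegraph model of gene expression, an adaptive
    Metropolis-adjusted Langevin sampler within a Gibbs scheme with automatic
    fallback from the cell-specific to the cell-pooled conversion model in
    unstable regions of parameter space, and an exact stochastic (Gillespie)
    simulator with full in-silico sequencing for validation on synthetic data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    optparse
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
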