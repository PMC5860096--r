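Package: motifclump
Title: Compound Poisson Statistics for Transcription Factor Motif Hits
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Statistics of transcription factor motif hits in DNA sequences
    under order-d Markov background models with strand/reversal symmetry.
    Computes exact discretized log-odds score distributions and
    significance thresholds for position frequency matrices, marginal and
    principal self-overlap probabilities on both strands, clump-size
    distributions, and compound Poisson and binomial models of the motif
    hit count, together with a simulation harness that validates the
    analytic models against empirical reference distributions.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    data.table,
    jsonlite,
    optparse,
    Rcpp,
    stats,
    utils,
    Biostrings
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
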