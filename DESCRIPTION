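Package: sparsefold
Title: Sparsified Minimum Free Energy RNA Secondary Structure Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Prediction of pseudoknot-free RNA secondary structures by free
    energy minimization under the Turner 2004 nearest-neighbor model, with
    full support for dangling-end contributions (no-dangle, always-dangle and
    exclusive-dangle models). The main engine uses candidate-list
    sparsification with linear rolling energy storage, reference-counted
    trace arrows with garbage collection, and three recovery strategies for
    dangle directions during space-efficient traceback; a dense Zuker-style
    dynamic program over the same energy model serves as an internal
    correctness oracle. Also provides hard-constraint folding, a Vienna
    parameter-file reader, loop-decomposition structure evaluation,
    base-pair accuracy metrics, and deterministic generators for random and
    dinucleotide-shuffled test sequences.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    jsonlite,
    Rcpp,
    stats
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
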