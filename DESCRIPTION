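Package: activeNER
Title: Active Learning for Clinical Named Entity Recognition with
    Cluster-Guided Uncertainty Sampling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Pool-based active learning for clinical named entity
    recognition (problem, treatment, and lab-test concepts). Implements a
    linear-chain conditional random field tagger with least-confidence
    uncertainty scoring, sentence clustering by latent Dirichlet
    allocation topic vectors and affinity propagation, and the CAUSE
    querying engine (cluster ranking by uncertainty followed by
    representative sampling), together with uncertainty and random
    baselines, a cross-validated simulation harness, learning-curve /
    area-under-learning-curve evaluation, annotation-session metrics, and
    a generator for topic-structured synthetic clinical corpora in
    BIO/CoNLL format.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    S4Vectors,
    IRanges,
    jsonlite,
    optparse
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
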