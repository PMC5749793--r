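Package: docsleep
Title: Permutation-Entropy Characterization of Sleep in Disorders of Consciousness
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for data-driven sleep characterization from polysomnography
    (PSG) when standard AASM staging is unreliable, as in patients with
    disorders of consciousness (DOC). Computes normalized permutation entropy
    per channel on consecutive 30 second epochs, performs group-level
    agglomerative hierarchical clustering with a healthy-anchored five-class
    dissimilarity cut-off, trains five-class sleep-stage classifiers (random
    forest or feedforward network) on labeled healthy recordings with
    leave-one-subject-out validation, and scores epoch-by-epoch patient
    hypnograms against eye-state video annotations with a binary sleep versus
    eyes-closed F1 statistic. A synthetic PSG generator produces healthy and
    DOC-like cohorts with controllable stage-wise complexity structure so the
    whole pipeline can be exercised and tested without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    signal,
    randomForest,
    nnet,
    ape,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mclust
Config/testthat/edition: 3
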