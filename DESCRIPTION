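Package: ethoscreen
Title: Behavioral Phenomics Stratification for Drosophila Sleep and
    Genetic-Interaction Screens
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: End-to-end pipeline for stratifying Drosophila disease models
    from multi-day video-tracking recordings: annotation of positional traces
    into movement and sleep states (10-s grid, 0.25 mm immobility rule,
    5-min sleep rule), extraction of sleep-architecture and activity features,
    non-negative matrix factorization of per-minute sleep ethograms into
    shared temporal components, hierarchical clustering of genotypes into
    behavioral subgroups, genetic-interaction scoring of electroretinogram
    amplitudes under a multiplicative non-interacting model (frequentist
    threshold rule and Bayesian highest-density-interval rule), and
    partition-concordance statistics (Jaccard similarity with a permutation
    null). Includes a synthetic-data generator with known ground truth so the
    whole pipeline is testable without recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    data.table,
    rjags,
    stats,
    utils
Suggests:
    coda,
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
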