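Package: pepVote
Title: Anticancer Peptide Classification with Composition Features and a
    Voting Ensemble
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Binary classification of anticancer peptides (ACP) versus
    non-anticancer peptides (NACP) from primary sequence. Provides four
    fixed-length sequence encoders (amino acid, dipeptide and tripeptide
    composition, and an improved pseudo amino acid composition built on
    nine physicochemical scales), greedy identity-based redundancy
    reduction, principal-component feature pruning, a weighted-voting
    ensemble of a radial-basis support vector machine, a random forest
    and a Gaussian naive Bayes classifier, a five-metric evaluation
    protocol, and a seedable two-class synthetic peptide generator for
    end-to-end benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    e1071,
    randomForest,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
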