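Package: FoldScanR
Title: Protein Fold Recognition with Fold-Specific PSSM Libraries
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Fold recognition for highly divergent ("twilight-zone") protein
    sequences using libraries of fold-specific position-specific scoring
    matrices (PSSMs). Builds per-fold PSSM libraries from redundancy-filtered
    sequence sets, scores queries against every library by local
    profile-sequence alignment with E-value and coverage filtering, summarises
    each query as a structural sequence profile (a vector of fold-specific
    scores), relates proteins by Pearson correlation of those profiles, and
    selects modelling templates by hierarchical clustering in
    identity-times-coverage feature space. Includes ROC/top-k evaluation
    machinery and a synthetic fold-family generator with controlled pairwise
    identity so the whole pipeline is testable without external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    Biostrings,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    ape,
    pROC
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'FoldScanR-package.R'
    'AllClasses.R'
    'RcppExports.R'
    'substitution.R'
    'align.R'
    'pssm-build.R'
    'scoring.R'
    'evaluation.R'
    'pssm-io.R'
    'seq-io.R'
    'synthetic.R'
    'templates.R'
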