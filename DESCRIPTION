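Package: parevol
Title: Molecular Evolution Toolkit for Parallel-Evolution Inference on Timed Phylogenies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for assessing temporal signal in heterochronous sequence data
    (root-to-tip regression, path-sampling and stepping-stone marginal-likelihood
    estimators, Bayes-factor model comparison of heterochronous versus isochronous
    sampling), epoch-partitioned transition/transversion bias estimation on
    time-calibrated trees, branch-site codon models of episodic positive selection
    with an epoch-level adaptive-divergence statistic, type I and type II functional
    divergence between sequence clusters with site-specific posterior probabilities,
    tree-based detection of coevolving residue pairs after physicochemical alphabet
    reduction, and Shine-Dalgarno-like motif scanning of untranslated regions.
    Includes seeded generators of synthetic trees, alignments and untranslated
    regions with known truth for calibration and power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    ape,
    Biostrings,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    Matrix,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
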