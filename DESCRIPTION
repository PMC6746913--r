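Package: sixmApred
Title: Prediction of DNA N6-Methyladenine Sites from Sequence Windows
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for building and evaluating sequence-based classifiers of
    DNA N6-methyladenine (6mA) sites. Adenine-centred 41-nt windows are
    encoded with three feature schemes (k-tuple nucleotide frequencies,
    per-position one-hot binary encoding, and the 12-dimensional natural
    vector of positional moments), classified with a bundled deterministic
    random forest, and evaluated with sensitivity, specificity, accuracy,
    the Matthews correlation coefficient, and ROC/AUC under k-fold,
    ratio-split, jackknife, and independent-test protocols. Includes
    motif-ratio-matched negative-set construction, a greedy sequence
    identity filter, a synthetic benchmark generator with tunable
    positional composition bias, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
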