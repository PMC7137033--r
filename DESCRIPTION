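Package: rnahmc
Title: Sequence-Based Prediction of RNA 5-Hydroxymethylcytosine Sites
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Predicts RNA 5-hydroxymethylcytosine (5hmC) modification sites
    from fixed-length sequence windows centered on a candidate cytosine.
    Windows are encoded as a 244-dimensional vector combining a per-position
    one-hot nucleotide code with 2-mer and 3-mer spectrum frequencies; the
    feature space is optimised in two stages (ANOVA F-value ranking followed
    by sequential forward search scored by cross-validated accuracy) and
    classified with a radial-basis-function support vector machine whose
    hyperparameters are grid-searched in log2 space.  Includes stratified
    five-fold cross-validation with Sn/Sp/ACC/MCC, ROC and precision-recall
    curves, a positional nucleotide enrichment report, a synthetic-data
    generator with planted compositional and positional signal for end-to-end
    testing, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    jsonlite,
    optparse,
    stats,
    utils,
    withr,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
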