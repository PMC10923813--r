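Package: sistrf
Title: Temporal Response Function Analysis of Speech-Induced Suppression
    in Dialogue EEG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to study how the brain encodes the acoustic features of
    continuous speech during natural two-person dialogue, and in particular
    the suppression of the response to one's own voice (speech-induced
    suppression). Implements lagged ridge-regression encoding models
    (multivariate temporal response functions) per EEG channel, frequency
    band and dialogue condition, with nested cross-validated regularization,
    a row-permutation significance test for model performance, group-level
    statistics (exact Wilcoxon signed-rank maps, threshold-free cluster
    enhancement with sign-flip permutations, paired Cohen's d and JZS Bayes
    factors, Bonferroni and Benjamini-Hochberg correction), and a lagged
    phase-locking analysis between the speech envelope and the EEG. A
    synthetic dyadic-dialogue generator with a known ground-truth response
    kernel and a self-speech gain provides an end-to-end testbed in which
    suppression is a controllable parameter.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    EBImage,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
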