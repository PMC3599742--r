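Package: aiia
Title: Adaptive Interbeat Interval Analysis of Heart Rate Variability
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Classifies heart-rate records from their interbeat (RR) interval
    dynamics. Successive RR-interval differences are symbolized by
    one-dimensional K-Means clustering into a letter alphabet, overlapping
    n-gram occurrence probabilities over the full gram vocabulary form the
    per-record feature vector, and records are classified under stratified
    k-fold cross-validation with a pluggable classifier interface (a fully
    specified Gaussian naive Bayes reference classifier is included).
    Also provides a seeded generator of labelled synthetic RR-interval
    records (atrial fibrillation, congestive heart failure, healthy
    young/elderly, apnea, uniform white noise) so the whole pipeline can be
    exercised without access to clinical recordings, plus readers and
    writers for plain-text RR lists and feature matrices and a command-line
    entry point.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    e1071,
    nnet,
    optparse,
    rpart,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
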