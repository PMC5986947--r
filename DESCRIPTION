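Package: nifclass
Title: Two-Stage SVM Classification of Nitrogen-Fixation Proteins
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Sequence-based identification and categorization of
    nitrogen-fixation (nif) proteins. Encodes protein sequences with six
    numeric feature schemes (amino acid composition, di-peptide composition,
    gap-pair composition, pseudo amino acid composition,
    composition-transition-distribution, and AAindex autocorrelation),
    trains support vector machines with kernel selection, and composes a
    two-stage classifier: nif versus non-nif, then assignment of stage-1
    positives to one of the six essential nif gene categories (nifB, nifD,
    nifE, nifH, nifK, nifN) subject to a probability threshold. Includes
    balanced-resampling cross-validation for imbalanced data, jackknife
    validation for the multi-class stage, confusion-count performance
    metrics, and a seeded synthetic sequence generator for offline testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    e1071,
    seqinr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
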