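Package: pepTTCA
Title: Tumor T Cell Antigen Prediction from Peptide Sequence Features
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies peptides as tumor T cell antigens (TTCA) or
    non-TTCA from sequence alone. Implements four fixed-length feature
    encoders (global protein sequence descriptors combining amino acid
    composition with composition/transition/distribution physicochemical
    descriptors; grouped amino acid and peptide composition; adaptive skip
    dipeptide composition; type-1 pseudo amino acid composition), MRMD
    feature ranking with incremental feature selection, SMOTE-Tomek hybrid
    resampling for class imbalance, and a random-forest classifier
    evaluated by stratified cross-validation with balanced accuracy, MCC
    and ROC AUC. A synthetic peptide generator with controllable
    compositional class signal supports fully offline testing of every
    stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    randomForest,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    e1071,
    optparse,
    jsonlite
Config/testthat/edition: 3
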