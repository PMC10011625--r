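Package: apaacsvm
Title: Apoptosis Protein Subcellular Localization via Amphiphilic Pseudo
    Amino Acid Composition and Support Vector Machines
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Predicts the subcellular location of apoptosis proteins from
    primary sequence. Protein sequences are encoded as amphiphilic pseudo
    amino acid composition (APAAC) vectors: the 20 amino acid occurrence
    frequencies extended with 2*lambda sequence-order correlation factors
    built from standardized hydrophobicity and hydrophilicity scales and
    weighted by omega. Classification uses a radial basis function kernel
    support vector machine with grid-searched hyperparameters; performance
    is estimated by the jackknife (leave-one-out) test and reported as
    per-class sensitivity, specificity and Matthews correlation coefficient
    together with overall accuracy. Includes a sweep over the (omega,
    lambda) grid, a seeded synthetic sequence generator for end-to-end
    testing without downloads, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    e1071,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    kernlab,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
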