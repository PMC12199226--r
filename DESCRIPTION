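Package: lesaQuant
Title: Quantifying Protein Adsorption on Polymer Microarrays from
    Targeted DIA LESA-MS/MS Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An end-to-end workflow for label-free quantification of
    protein adsorption on polymer microarray spots sampled by liquid
    extraction surface analysis tandem mass spectrometry (LESA-MS/MS).
    Provides in-silico tryptic digestion with disulfide-aware free-peptide
    filtering, a data model for targeted data-independent acquisition (DIA)
    runs, spectral-library identification by cosine similarity, MS1
    extracted-intensity quantification with replicate aggregation and
    signal-to-noise filtering, atom-signature fragment descriptors for
    polymer monomers, and sparse multiple linear regression fitted by
    expectation maximization after LASSO feature selection, with bootstrap
    evaluation. A synthetic-data module generates ground-truthed DIA runs
    and descriptor matrices so every stage can be tested without external
    data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    glmnet,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    mzR,
    ChemmineR,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
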