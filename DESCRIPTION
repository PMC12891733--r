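Package: vaxtcr
Title: Immunomonitoring of Mutant-KRAS Peptide Vaccine Trials
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for analysing the immunomonitoring readouts of
    neoantigen peptide vaccine trials targeting mutant KRAS: reading and
    aggregating bulk TCR-beta rearrangement tables (AIRR-C and
    Adaptive-style TSV), calling antigen-stimulated clonotype expansion
    with a one-sided Fisher exact test and Benjamini-Yekutieli FDR
    control, classifying cross-reactive and public clonotypes,
    high-similarity CDR3 matching by optimal string alignment distance,
    ELISPOT responder scoring against the 2.77-standard-deviation
    threshold, Kaplan-Meier/log-rank outcome stratification, and a
    seeded synthetic-data generator with ground truth for end-to-end
    validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    graphics,
    jsonlite,
    stats,
    survival,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
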