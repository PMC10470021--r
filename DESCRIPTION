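Package: tcrbalance
Title: TCR Clonotype Tracking, ELISPOT Positivity Calls, and
    Effector-Target Balance Modelling for Neoantigen Vaccine Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing whether vaccine-induced neoantigen-specific
    T cells enrich in bone marrow. Ingests bulk TCR alpha/beta clonotype
    tables (AIRR Rearrangement TSV or a minimal TSV dialect), applies
    read-count and culture-fraction filters, tracks clonotypes across
    baseline and end-of-trial samples, and summarises the specific-clonotype
    fraction per patient. Implements normalized-count computation and the
    distribution-free resampling (DFR/DFR2x) positivity test for ELISPOT
    replicate wells, and a closed-form effector-target balance model giving
    kills per specific T cell, total kill time, and the maximal variant
    allele fraction controllable by cellular immunity. A synthetic-repertoire
    generator with known ground truth supports end-to-end recovery testing.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
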