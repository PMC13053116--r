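Package: genoprev
Title: Aggregate Allele Frequency and Genetic Prevalence Estimation for
    Recessive Disease
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates carrier frequency and genetic prevalence of
    autosomal-recessive disease from ancestry-stratified reference allele
    counts (gnomAD-style AC/AN/nhomalt tables), following the
    Hardy-Weinberg aggregate allele frequency approach used in genetic
    prevalence studies of rare recessive disorders. Provides readers for
    ClinVar-, HGMD- and predicted loss-of-function variant candidate
    tables, variant normalization and cross-source deduplication,
    allele-count based curation triage, conservative and relaxed
    inclusion sets, per-ancestry-group prevalence estimates with "1 in N"
    formatting, population projections of expected affected individuals,
    and deterministic synthetic cohort generators for end-to-end testing,
    including a fixture reproducing the published GBE1 (glycogen storage
    disease type IV) estimates.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    vcfR
Config/testthat/edition: 3
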