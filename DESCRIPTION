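Package: msiconcord
Title: Concordance of Mismatch-Repair Deficiency Assays in Lynch Syndrome
    Urothelial Tumors
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to compare three tests for mismatch-repair (MMR)
    deficiency in Lynch syndrome-associated urothelial tumors: an amplicon
    sequencing-based microsatellite-instability (MSI) classifier that scores
    mononucleotide-repeat markers with a naive-Bayes log-likelihood ratio,
    a fragment-length rule classifier in the style of the Promega MSI
    Analysis System run without matched normal DNA, and an
    immunohistochemistry loss rule for the four MMR proteins. The package
    joins the three assays through an exact diagnostic-concordance
    framework (exact McNemar test, Wilson and Clopper-Pearson intervals,
    Fisher's exact test) and ships a synthetic-cohort generator that
    emulates FFPE tumor material - PCR stutter, tumor purity, gene-specific
    somatic deletion effect sizes, and block-age-dependent dropout - so the
    whole pipeline is testable without access to patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
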