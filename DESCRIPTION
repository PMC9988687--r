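Package: gepbridge
Title: Bridging Gene-Expression Classifiers from Microarray to qRT-PCR
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Transfers a fixed linear gene-expression classifier from a
    source platform (microarray log2 intensities) to a target platform
    (qRT-PCR delta-Ct values) by per-feature multiple linear regression and
    coefficient substitution, and evaluates the bridged classifier by
    leave-one-out cross-validated ROC analysis. Includes reference-gene
    screening by expression window, differential-expression exclusion and
    robust-Z outlier counts; delta-Ct computation against two reference
    genes with unstable-target flagging; conversions between normalized and
    raw delta-Ct model representations; probe-to-transcript overlap
    aggregation for cross-platform concordance; and a synthetic
    paired-platform cohort generator for end-to-end testing. Ships the
    published Kawasaki disease classifier (KiDs-GEP) weights in all three
    representations as packaged fixtures.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    pROC,
    MASS,
    Biostrings,
    stats,
    utils
Suggests:
    limma,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
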