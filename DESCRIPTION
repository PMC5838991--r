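Package: oncosieve
Title: Tumor-Only Somatic Variant Filtering and Clinical Interpretation
    for Targeted Panels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Rule-based interpretation of tumor-only targeted-panel
    sequencing: a panel-of-normals blacklist of recurrent sequencing
    artifacts, an ordered somatic filtering cascade with COSMIC-tiered
    variant-allele-frequency and read-support thresholds, log2-ratio
    copy-number classification, tumor mutational burden, gene-by-patient
    cohort profiling with pathway groupings, and matching of kept
    alterations against a clinical-actionability knowledge base.  Ships a
    fully labelled synthetic cohort generator so every stage is testable
    without patient data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    GenomicRanges,
    IRanges,
    GenomeInfoDb,
    S4Vectors,
    vcfR,
    jsonlite,
    stats,
    utils,
    methods
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
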