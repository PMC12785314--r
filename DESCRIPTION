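Package: rflpmx
Title: Multiplex Fluorescent PCR-RFLP Genotyping of FV Leiden and Prothrombin G20210A
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computational interpretation layer for a multiplex fluorescent
    PCR-RFLP assay detecting the thrombosis risk variants Factor V Leiden
    (F5 c.1601G>A) and prothrombin F2 G20210A. Calls genotypes from
    capillary-electrophoresis fragment peak tables, validates MnlI and
    HindIII digestion controls, monitors sample identity and detects DNA
    contamination through two co-amplified short tandem repeats (FGA and
    SE33), performs in-silico restriction digestion of amplicon sequences,
    and ships a synthetic peak-table simulator that reproduces the assay's
    statistical structure (heterozygous peak-height ratios, stutter peaks,
    digestion failures and two-person DNA mixtures) so that the full
    validation study can be re-run in silico.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
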