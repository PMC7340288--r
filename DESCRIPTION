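Package: mmrscreen
Title: Germline Variant Prioritization for Mismatch-Repair Pathway Gene Panels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for prioritizing germline variants from targeted
    sequencing of the 22 genes of the DNA mismatch-repair (MMR) pathway.
    Provides HGVS c.-notation parsing with intronic offsets, region-stratified
    frequency and ClinVar filtering with per-stage accounting, position-weight-
    matrix splice-site scoring (percent-score convention) with new-site and
    cryptic-activation calls, an ACMG/AMP five-class evidence rule engine,
    5'UTR transcription-factor binding-site allele-preference scoring from
    JASPAR-format frequency matrices, 3'UTR microRNA seed-site disruption
    calls, variant-allele-fraction and coverage QC, and a seeded synthetic
    cohort generator for end-to-end validation against injected truth.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils,
    vcfR
Suggests:
    rtracklayer,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
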