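Package: panelvote
Title: Gene-Panel Variant Prioritization by Ensemble Predictor Voting
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Reusable pipeline for prioritizing annotated gene-panel
    sequencing variants by consensus voting across 19 in-silico
    pathogenicity predictors under two selection hypotheses (a panel-free
    vote cutoff and a panel-restricted vote cutoff), followed by
    reconciliation against ClinVar assertions and pedigree segregation
    evidence (including de novo and germline-mosaicism patterns).
    Includes a clinical cohort module (Van der Burgt diagnostic scoring,
    dysmorphology feature frequency tables stratified by age band and
    ancestry, genotype-phenotype summaries) and a deterministic
    synthetic-data generator so every stage is testable without access
    to patient-level sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    withr
Config/testthat/edition: 3
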