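Package: phenotext
Title: Translate, De-Identify, and Summarize Clinical Reports into HPO Terms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An offline pipeline for clinical phenomics text processing:
    expands clinical abbreviations from a curated dictionary, translates
    reports through a pluggable deterministic engine contract, de-identifies
    protected health information (PHI) with rule-based person, date and
    location recognizers under a hybrid allowlist/denylist gazetteer scheme,
    and summarizes the de-identified text into Human Phenotype Ontology (HPO)
    terms with high/low confidence flags derived from negation and
    family-member cues, including capture of quantitative evidence. Ships an
    evaluation kit (TP/FP/FN accounting, severity filtering, rounded
    recall/precision/F1) and a synthetic-report generator with
    machine-readable gold annotations so every stage is testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
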