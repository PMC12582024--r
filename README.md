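# phenotext

Translate, de-identify, and summarize clinical reports into Human
Phenotype Ontology (HPO) terms — fully offline.

Rare-disease genomics runs on two scarce resources: deep phenotype
descriptions and the freedom to share them. A consultation report holds
both problems at once — it is written in the clinic's language, it is full
of protected health information (PHI: names, dates, places), and its
clinical content is unstructured prose. `phenotext` is an R implementation
of the standard pipeline for this workflow, built for environments where
health data cannot leave the premises:

1. **expand** clinical abbreviations from a curated dictionary,
2. **translate** through a pluggable, deterministic engine contract
   (passthrough and glossary word-substitution engines ship with the
   package; neural translation can be plugged in behind the same
   interface),
3. **de-identify** with rule-based person / date / location recognizers
   under a hybrid gazetteer scheme — allowlists of disease eponyms, drugs
   and gene symbols *veto* redaction so clinical content survives, while a
   geographic denylist *forces* it,
4. **summarize** the de-identified text into HPO terms by sentence-level
   lemmatized token-subset matching, flagged `high` confidence when
   affirmed for the proband and `low` when the sentence is negated or
   about a family member, with nearby measurements (`-2.5 SD`,
   `3rd percentile`) captured as quantitative evidence.

Formally, a term $t$ with label token sets $L(t)$ matches sentence $s$
with lemma set $T(s)$ iff $\exists \ell \in L(t): \ell \subseteq T(s)$.
Evaluation uses the usual confusion accounting — missed PHI is a false
negative, over-redaction a false positive, likewise missed/excess HPO
terms — with recall $= \mathrm{TP}/(\mathrm{TP}+\mathrm{FN})$ and
precision $= \mathrm{TP}/(\mathrm{TP}+\mathrm{FP})$ reported as half-up
integer percentages, F1 from unrounded fractions, and false positives
gradable by a major/moderate/minor severity taxonomy.

The package also ships an **evaluation kit** (span-overlap PHI scoring,
exact-id HPO scoring, severity filtering) and a **synthetic-report
generator** that plants machine-readable gold truth (PHI spans,
abbreviations, affirmed/negated/family symptom phrases, measurements,
plus designed hard-case probes), so the entire pipeline is testable with
no external data, no model weights and no network.

## Worked example

```r
library(phenotext)

idx <- build_synonym_index(load_ontology(
  system.file("extdata", "fixture.obo", package = "phenotext")))
cfg <- pipeline_config(
  idx,
  abbrev = abbreviation_dictionary(c(ID = "intellectual disability")),
  allowlists = list(gazetteer(c("Noonan", "Iso Kikuchi"), "medical_name")),
  denylist = gazetteer(c("Montpellier", "Nîmes"), "location"))

report <- paste(
  "Mr Dupont was seen on 12/03/2023 in Montpellier.",
  "ID was suspected at an early age.",
  "The patient has seizures.",
  "His mother has microcephaly.",
  "No cleft palate was seen.",
  "A diagnosis of Noonan syndrome is being considered.")

res <- process_report(report, cfg, doc_id = "example")
cat(res$deid_text)
#> Mr <PERSON> was seen on <DATE_TIME> in <LOCATION>. intellectual
#> disability was suspected at an early age. The patient has seizures.
#> His mother has microcephaly. No cleft palate was seen. A diagnosis of
#> Noonan syndrome is being considered.

res$hits[, c("term_id", "label", "confidence", "reason", "count")]
#>      term_id                   label confidence   reason count
#> 1 HP:0001249 Intellectual disability       high affirmed     1
#> 2 HP:0001250                 Seizure       high affirmed     1
#> 3 HP:0000252            Microcephaly        low   family     1
#> 4 HP:0000175            Cleft palate        low  negated     1
```

Reading the output: the name, date and city were redacted, but the
allowlisted eponym "Noonan" survived; the abbreviation "ID" was expanded
*before* matching and recovered as a high-confidence term; the mother's
symptom and the explicitly negated finding are reported but flagged
low-confidence — present for review, excluded from a high-confidence
export. `write_hits_csv()` and `write_phenotips_json()` serialize the hit
list (family-member findings go to a separate `family_features` array in
the JSON); `run_pipeline()` does all of the above for a directory of
reports and also writes the per-report span audit.

A command-line front end with `run`, `deid`, `summarize`, `eval` and
`synth` subcommands lives at `inst/cli/phenotext.R`.

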