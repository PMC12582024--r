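---
title: "Methods: clinical report de-identification and HPO summarization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: clinical report de-identification and HPO summarization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phenotext)
```

## The problem

Rare-disease genomics depends on sharing deep phenotype descriptions across
institutions and languages. A clinical report in French is useless to a
matchmaking service until it has been translated, stripped of protected
health information (PHI), and condensed into Human Phenotype Ontology (HPO)
terms. Doing this by hand is slow and inconsistent; doing it with cloud
services violates data-locality rules for health data. `phenotext`
implements the whole chain as an offline, rule-based pipeline whose every
decision is auditable, plus the evaluation machinery needed to score it.

A report moves through four stages:

1. **Abbreviation expansion.** Whole-token, case-sensitive replacement from
   a curated dictionary ("ID" → "intellectual disability"). Case matters:
   clinical abbreviations are case-bearing and their lowercase forms
   ("id") are ordinary words. Where keys overlap at a position the longest
   key wins, and expansions are never re-scanned, so expansion terminates
   and is idempotent whenever no expansion contains a key. Every
   replacement is recorded in an edit map; applying the map to the input
   reproduces the output exactly, which is what lets gold annotations be
   carried across stages.
2. **Translation.** A deterministic engine contract: any function from
   sentence to English sentence. The package ships a passthrough engine
   and a glossary engine (whole-token word substitution). Real neural
   translation can be plugged in behind the same interface; nothing
   downstream depends on more than sentence-count conservation and
   determinism. The glossary engine is applied document-wide so that its
   edit map stays token-level and spans of untranslated tokens (names,
   dates) survive remapping exactly.
3. **De-identification.** Rule-based recognizers for dates (numeric
   formats, month names in English and the source language, and bare years
   next to a cue word such as "born"), persons (capitalized sequences
   after a title trigger — Mr, Mrs, Dr, née, born — plus any name-gazetteer
   occurrence) and locations (every whole-word occurrence of a geographic
   denylist phrase). A hybrid gazetteer scheme then arbitrates: allowlists
   of medical eponyms, drugs and gene symbols *veto* detector spans — so
   "Noonan" after "Dr" is not lost, and a word inside an allowlisted
   multi-word phrase such as "Iso Kikuchi" survives — while the location
   denylist *forces* redaction and is exempt from every veto. Direct
   allow/deny conflicts resolve to redaction: when in doubt, privacy wins
   over clinical completeness, because an identity leak is the most severe
   error class. Surviving spans are merged (same-category overlaps and
   zero-gap adjacencies coalesce; cross-category overlaps keep the
   earlier-starting span, ties broken PERSON > DATE_TIME > LOCATION > ID)
   and replaced by `<CATEGORY>` placeholders, leaving all other bytes
   untouched.
4. **HPO summarization.** Concept recognition is sentence-level token-set
   containment: a term matches a sentence when the normalized token set of
   one of its labels (name or any OBO synonym, all synonym scopes) is a
   subset of the sentence's lemma set. Normalization lowercases, folds
   accents, strips punctuation, lemmatizes and drops a small fixed English
   stopword list. Sentences containing a family-member cue yield
   `low`-confidence `family` hits; otherwise a negation cue yields
   `low`/`negated`; otherwise the hit is `high`/`affirmed`. Per document a
   term appears once: any affirmed occurrence promotes it to high
   confidence, otherwise the earliest occurrence's reason is kept. Negated
   terms are reported (flagged low) rather than dropped; distinguishing
   "absent" from "low-confidence" would need real negation scoping and is
   out of scope. The nearest measurement expression in the evidence
   sentence (`-2.5 SD`, `3rd percentile`, `48 cm`) is attached as
   quantitative evidence; ties in token distance go to the earlier
   expression. Summarization runs on the *de-identified* text so that the
   exported evidence is shareable; placeholders are excluded from
   tokenization and can never match a term.

## Design choices worth defending

**Sentence-scoped cues.** Negation and family context are judged for the
whole sentence, not a token window. This deliberately over-triggers ("his
mother is well but the patient has seizures" would flag the seizure
sentence as family context if they shared a sentence) — but misclassified
hits land in the low-confidence channel rather than disappearing, and the
channel structure is exactly what downstream users review. When family and
negation cues co-occur, family wins: "his mother has no seizures" is a
statement about the family member.

**Accent folding preserves length.** All case/accent folding is a
character-for-character table (`fold_text()`), not transliteration, so an
offset computed on folded text is valid in the original. This is what
makes gazetteer scanning, span merging and redaction composable without an
offset-translation layer. The cost is that ligatures (œ, æ) are not
folded; none of the shipped lexicons need them.

**Lemmatization is a table plus suffix rules.** A deterministic exception
table (irregular plurals) and English plural-suffix stripping. That is
deliberately weaker than a statistical lemmatizer, but it is
engine-independent, reproducible, and sufficient for ontology labels,
which are noun phrases. The normalizer accepts a pluggable `lemmatizer`
function for callers who need more.

**Exact-id evaluation.** HPO predictions are scored on exact term ids with
no ancestor credit, and PHI detection is credited on one-character span
overlap with category ignored: the confusion matrix counts detection
events, while the severity taxonomy (major = identity leak or redacted
diagnosis; moderate = indirect identifier or redacted clinical term;
minor = redacted filler) carries the graded judgment. Percentages are
rounded half-up to integers, and F1 is computed from unrounded fractions —
this is the rounding under which the published benchmark counts reproduce
their printed metrics (443/449 → 99%, 443 vs 133 FP → 77%, 133−69 minor
FPs → 87%, 332/426 → 78%, 332/50 → 6.6, 125/255 → 49%, 207/426 → 49%).
The per-report averaged F1 figures the benchmark also reports cannot be
recomputed from published data (per-report counts are not public), and
the high-confidence precision figure is printed at a rounding its own
counts do not reproduce (207/227 → 91%), so neither is asserted anywhere.

## The synthetic corpus: what it does and does not show

The generator (`generate_corpus()`) plants machine-readable truth in
templated reports: person/date/location PHI drawn from pools that are
*also* exported as the detector gazetteers, abbreviations, affirmed /
negated / family symptom phrases with optional measurements, and two probe
families modeled on the benchmark's documented hard cases — a
descriptive-syndrome sentence ("This syndrome is typically associated
with…", recorded in gold as *not* expected, so it surfaces any premature
symptom attribution as a designed false positive) and an allowlisted
eponym after a title ("…description by Dr Noonan", which the person
detector must flag and the allowlist must rescue).

Defaults are the benchmark dataset's per-report medians: 50 reports,
15 PHI (split 166:231:51 across person/date/location, the benchmark's
channel proportions), 3 abbreviations and 7 HPO terms per report. Rates
the benchmark does not publish were fixed once at values typical of
genetics consultation notes and are not tuned: 20% of symptom phrases
negated, 15% in family context, 30% of affirmed phrases carrying a
measurement, a probe sentence in 10% and an eponym sentence in 20% of
reports, and 2–4 filler sentences. The "fr-like" mode builds the same
reports from a pseudo-French vocabulary that the glossary engine maps
token-for-token to English, so the translation stage is exercised without
model weights.

Because detectors are configured with the generator's own pools, pipeline
closure on this corpus is exact: 100% PHI recall, 100% HPO recall, all
confidence labels matching gold. That is a *consistency* property — it
shows the stages compose without losing or corrupting information, and it
is the fixture analogue of the benchmark's 99% / 78% on real reports. It
does not show robustness to real clinical prose: free-text name variants,
OCR noise, unlisted locations, and discourse-level negation are all
outside what templated text can probe, which is precisely why the
evaluation kit and gold-TSV interface exist for scoring real annotated
data.

## Numerical and degenerate-input conventions

All spans are 0-based half-open character intervals; merging treats
zero-gap same-category spans as one detection. Empty documents, empty
lexicons and zero-count confusion matrices are valid inputs: metrics with
a zero denominator return `defined = FALSE` rather than an error; a label
that normalizes to the empty token set is skipped with a warning rather
than poisoning the index. Fixture problem sizes used in the shipped test
suite — a 42-term ontology, 50-report corpora (~1,400 sentences) for the
oracle-equivalence and closure properties, 5–10 reports elsewhere — keep
the whole suite under a minute while exceeding the 1,000-sentence floor
the matcher-equivalence property is stated over.

## A worked example

```{r example}
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
res$hits[, c("term_id", "label", "confidence", "reason", "count")]
```

The person, date and location are replaced by placeholders while "Noonan"
survives; the expanded abbreviation is recovered as a high-confidence
term; the family-context and negated symptoms are present but flagged low.

## Known limitations

- Person detection without a name gazetteer requires a title trigger;
  bare names in running text are invisible to it. The recognizer is
  pluggable for exactly this reason.
- Negation and family scoping is sentence-global; clause-level scoping is
  future work, as is labeling negated terms "absent".
- The lemmatizer handles English plural morphology only; verbal
  inflection and derivational variants rely on ontology synonyms.
- Translation quality is whatever the plugged-in engine provides; the
  shipped engines are deterministic stand-ins for testing, not
  translators.
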