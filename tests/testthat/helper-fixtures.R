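# Fixtures are built in code so the suite has no binary or external data.

# A minimal hand-written OBO: 5 HP terms, one obsolete, one stanza with two
# synonym lines.
tiny_obo_text <- function() {
  paste(
    "format-version: 1.2",
    "ontology: hp-tiny",
    "",
    "[Term]",
    "id: HP:0000001",
    "name: Phenotypic abnormality",
    "",
    "[Term]",
    "id: HP:0001250",
    "name: Seizure",
    "synonym: \"Epileptic seizure\" EXACT []",
    "synonym: \"Seizures\" EXACT []",
    "is_a: HP:0000001 ! root",
    "",
    "[Term]",
    "id: HP:0000252",
    "name: Microcephaly",
    "synonym: \"Small head\" BROAD []",
    "is_a: HP:0000001 ! root",
    "",
    "[Term]",
    "id: HP:0000175",
    "name: Cleft palate",
    "is_a: HP:0000001 ! root",
    "",
    "[Term]",
    "id: HP:0001249",
    "name: Intellectual disability",
    "synonym: \"Mental retardation\" RELATED []",
    "is_a: HP:0000001 ! root",
    "",
    "[Term]",
    "id: HP:0009999",
    "name: obsolete Seizure-like episodes",
    "is_obsolete: true",
    "replaced_by: HP:0001250",
    "",
    sep = "\n")
}

write_tiny_obo <- function() {
  p <- tempfile(fileext = ".obo")
  writeLines(tiny_obo_text(), p, sep = "")
  p
}

tiny_ontology <- function() load_ontology(write_tiny_obo())

tiny_index <- function() build_synonym_index(tiny_ontology())

# Full-vocabulary fixture ontology + generator-matched lexicons and the
# pipeline config closing over them (passthrough engine, English corpus).
synth_ontology <- function(seed = 1L, n_terms = 42L) {
  p <- tempfile(fileext = ".obo")
  writeLines(make_fixture_ontology(seed, n_terms), p, sep = "")
  load_ontology(p)
}

synth_setup <- function(seed = 1L, language = "en") {
  ont <- synth_ontology(seed)
  lex <- synth_lexicons(language)
  idx <- build_synonym_index(ont)
  engine <- if (language == "fr") make_glossary_engine(lex$glossary, "fr")
            else make_passthrough_engine("en")
  cfg <- pipeline_config(idx, abbrev = lex$abbrev, engine = engine,
                         allowlists = lex$allowlists,
                         denylist = lex$denylist,
                         name_gazetteer = lex$names, language = language)
  list(ontology = ont, lexicons = lex, index = idx, config = cfg)
}

# Remap gold spans (raw-text offsets) into the de-identification stage's
# coordinate system using the pipeline's per-stage edit maps.
remap_gold <- function(gold_spans, result) {
  remap_spans(remap_spans(gold_spans, result$expansion_edits),
              result$translation_edits)
}

# A redaction-span frame over the first occurrence of `surface` in `text`.
redaction_spans_for_test <- function(text, surface, category, source) {
  at <- regexpr(surface, text, fixed = TRUE)
  stopifnot(at > 0)
  start <- as.integer(at) - 1L
  data.frame(start = start, end = start + nchar(surface),
             category = category, source = source, surface = surface,
             placeholder = paste0("<", category, ">"),
             stringsAsFactors = FALSE)
}

# Independent brute-force matcher: for each term label (name or synonym,
# straight from the ontology records), a sentence matches iff the label's
# normalized token set is contained in the normalized token set of the raw
# sentence text. Used as the oracle against summarize_document /
# match_sentence.
oracle_match_sentence <- function(sentence_text, ontology) {
  toks <- normalize_phrase(sentence_text)
  hits <- character(0)
  for (t in ontology) {
    if (t$obsolete) next
    for (lab in c(t$name, t$synonyms)) {
      lt <- normalize_phrase(lab)
      if (length(lt) && all(lt %in% toks)) {
        hits <- c(hits, t$id)
        break
      }
    }
  }
  sort(unique(hits))
}
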