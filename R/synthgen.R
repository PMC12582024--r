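# Synthetic clinical reports with machine-readable gold truth: planted PHI
# (names, dates, locations), abbreviations, affirmed/negated/family symptom
# phrases and measurements, plus a fixture ontology and generator-matched
# lexicons. Everything is deterministic per seed, so the full pipeline is
# testable end-to-end with no external data.

# Phenotype vocabulary the fixture ontology draws from. `fr` holds a
# token-per-token pseudo-French rendering used by the "fr-like" corpus mode
# together with the glossary translation engine (tokens that are cognates
# need no glossary entry; token order is irrelevant to set-subset matching).
.phenotype_pool <- list(
  list(name = "Seizure", syn = c("Epileptic seizure", "Seizures"),
       fr = "crises"),
  list(name = "Microcephaly", syn = "Small head", fr = "microcéphalie"),
  list(name = "Macrocephaly", syn = "Large head", fr = "macrocéphalie"),
  list(name = "Muscular hypotonia", syn = "Low muscle tone",
       fr = "hypotonie musculaire"),
  list(name = "Intellectual disability", syn = "Mental retardation",
       fr = "déficience intellectuelle"),
  list(name = "Global developmental delay", syn = character(0)),
  list(name = "Ataxia", syn = character(0), fr = "ataxie"),
  list(name = "Nystagmus", syn = character(0), fr = "nystagmus"),
  list(name = "Scoliosis", syn = character(0), fr = "scoliose"),
  list(name = "Hepatomegaly", syn = "Enlarged liver",
       fr = "hépatomégalie"),
  list(name = "Splenomegaly", syn = "Enlarged spleen"),
  list(name = "Short stature", syn = "Decreased body height",
       fr = "petite taille"),
  list(name = "Tall stature", syn = character(0)),
  list(name = "Cleft palate", syn = character(0), fr = "fente palatine"),
  list(name = "Atrial septal defect", syn = character(0)),
  list(name = "Ventricular septal defect", syn = character(0)),
  list(name = "Hearing impairment", syn = "Hearing loss"),
  list(name = "Visual impairment", syn = character(0)),
  list(name = "Strabismus", syn = "Squint", fr = "strabisme"),
  list(name = "Ptosis", syn = "Drooping eyelid", fr = "ptosis"),
  list(name = "Hypertelorism", syn = character(0)),
  list(name = "Micrognathia", syn = character(0)),
  list(name = "Macroglossia", syn = character(0)),
  list(name = "Polydactyly", syn = character(0)),
  list(name = "Syndactyly", syn = character(0)),
  list(name = "Clinodactyly", syn = character(0)),
  list(name = "Talipes equinovarus", syn = "Clubfoot"),
  list(name = "Spasticity", syn = character(0), fr = "spasticité"),
  list(name = "Dysarthria", syn = character(0)),
  list(name = "Dysphagia", syn = "Swallowing difficulty"),
  list(name = "Failure to thrive", syn = character(0)),
  list(name = "Obesity", syn = character(0), fr = "obésité"),
  list(name = "Feeding difficulties", syn = character(0)),
  list(name = "Gait disturbance", syn = "Abnormal gait"),
  list(name = "Tremor", syn = character(0), fr = "tremblements"),
  list(name = "Chorea", syn = character(0)),
  list(name = "Hypoglycemia", syn = character(0)),
  list(name = "Anemia", syn = character(0), fr = "anémie"),
  list(name = "Thrombocytopenia", syn = character(0)),
  list(name = "Nail dysplasia", syn = "Onychodysplasia")
)

.synth_surnames <- c("Dupont", "Martin", "Bernard", "Moreau", "Lefevre",
                     "Garnier", "Rousseau", "Blanchard", "Girard", "Lambert",
                     "Fontaine", "Chevalier", "Perrin", "Marchand", "Dumas",
                     "Leclerc", "Renard", "Baron", "Colin", "Picard")

.synth_locations <- c("Montpellier", "Nîmes", "Paris", "Lyon",
                      "Marseille", "Toulouse", "Nantes", "Lille", "Bordeaux",
                      "Strasbourg", "Rennes", "Grenoble", "Dijon", "Angers",
                      "Avignon", "Perpignan", "Béziers", "Sète",
                      "Alès", "Nancy")

.synth_eponyms <- c("Noonan", "Marfan", "Kabuki", "Rett", "Angelman",
                    "Dravet", "West", "Iso Kikuchi", "Prader-Willi",
                    "Cornelia de Lange")

.synth_drugs <- c("valproate", "levetiracetam", "risperidone", "melatonin",
                  "methylphenidate", "baclofen", "topiramate", "clobazam")

.synth_genes <- c("MECP2", "SCN1A", "PTPN11", "FBN1", "UBE3A", "NIPBL",
                  "KMT2D", "CDKL5", "STXBP1", "ARID1B")

# Abbreviations whose expansion is itself an ontology term name contribute a
# gold phenotype record when planted; the others are plain clinical jargon.
.synth_abbrev_term <- c(ID = "Intellectual disability",
                        FTT = "Failure to thrive",
                        GDD = "Global developmental delay",
                        ASD = "Atrial septal defect")
.synth_abbrev_plain <- c(HC = "head circumference",
                         OFC = "occipitofrontal circumference",
                         EEG = "electroencephalogram",
                         MRI = "magnetic resonance imaging",
                         PT = "physical therapy")

# Pseudo-French -> English glossary backing the fr-like corpus mode.
.fr_glossary <- c(
  # template vocabulary
  "Le" = "The", "La" = "The", "le" = "on", "présente" = "shows",
  "Pas" = "No", "de" = "of", "observée" = "observed",
  "mère" = "mother", "frère" = "brother", "a" = "has",
  "été" = "been", "vu" = "seen", "vue" = "seen", "par" = "by",
  "habite" = "lives", "à" = "at", "était" = "was",
  "noté" = "noted", "famille" = "family",
  "Examen" = "Examination", "Ce" = "This", "est" = "is",
  "associé" = "associated", "avec" = "with",
  "Décrit" = "Described", "Né" = "Born", "en" = "in",
  "suivi" = "monitoring", "prévu" = "planned",
  # phenotype vocabulary
  "crises" = "seizures", "microcéphalie" = "microcephaly",
  "macrocéphalie" = "macrocephaly", "hypotonie" = "hypotonia",
  "musculaire" = "muscular", "déficience" = "disability",
  "intellectuelle" = "intellectual", "ataxie" = "ataxia",
  "scoliose" = "scoliosis", "hépatomégalie" = "hepatomegaly",
  "petite" = "short", "taille" = "stature", "fente" = "cleft",
  "palatine" = "palate", "strabisme" = "strabismus",
  "obésité" = "obesity", "tremblements" = "tremors",
  "spasticité" = "spasticity", "anémie" = "anemia")

#' Generator-matched fixture lexicons
#'
#' The same name and location pools the generator plants are exported as the
#' detector gazetteers, so synthetic-corpus evaluations close at 100%
#' recall by construction. Allowlists carry disease eponyms, drugs and gene
#' symbols; the denylist carries the location pool.
#'
#' @param language `"en"` or `"fr"` (language code recorded on the
#'   abbreviation dictionary; entries are shared).
#' @return List with `abbrev` (`ptx_abbrev`), `allowlists` (list of three
#'   allow gazetteers), `denylist` (location gazetteer), `names`
#'   (`ptx_gazetteer` of surnames), `name_pool`, `location_pool` (surface
#'   strings), `glossary` (named vector for the fr-like engine).
#' @export
synth_lexicons <- function(language = "en") {
  abbrev <- abbreviation_dictionary(
    c(.synth_abbrev_term, .synth_abbrev_plain), language = language)
  list(
    abbrev = abbrev,
    allowlists = list(
      gazetteer(.synth_eponyms, "medical_name"),
      gazetteer(.synth_drugs, "drug"),
      gazetteer(.synth_genes, "gene")
    ),
    denylist = gazetteer(.synth_locations, "location"),
    names = gazetteer(.synth_surnames, "medical_name"),
    name_pool = .synth_surnames,
    location_pool = .synth_locations,
    glossary = .fr_glossary
  )
}

#' Generate a fixture ontology in OBO format
#'
#' Emits a valid OBO 1.2 file with `n_terms` HP-style terms: a root, a
#' sampled subset of the phenotype vocabulary (at least 30% carrying
#' synonyms), an `is_a` tree rooted at the first term and exactly one
#' obsolete term with a `replaced_by` pointer. Deterministic per seed.
#'
#' @param seed Integer seed.
#' @param n_terms Total number of terms (>= 5), including root and the
#'   obsolete term.
#' @return A single character scalar: the OBO file text.
#' @export
make_fixture_ontology <- function(seed = 1L, n_terms = 30L) {
  if (n_terms < 5) stop("n_terms must be at least 5")
  n_body <- n_terms - 2L # minus root and obsolete term
  if (n_body > length(.phenotype_pool)) {
    stop("fixture vocabulary supports at most ",
         length(.phenotype_pool) + 2L, " terms")
  }
  set.seed(seed)
  # stratified sampling keeps the >= 30% synonym guarantee at any size
  has_syn <- which(vapply(.phenotype_pool, function(e) length(e$syn) > 0,
                          logical(1)))
  n_syn <- min(length(has_syn), ceiling(0.3 * n_body))
  take_syn <- sample(has_syn, n_syn)
  rest <- sample(setdiff(seq_along(.phenotype_pool), take_syn),
                 n_body - n_syn)
  picks <- .phenotype_pool[sort(c(take_syn, rest))]
  ids <- sprintf("HP:%07d", 200L + seq_len(n_body))
  root_id <- "HP:0000118"
  out <- c("format-version: 1.2",
           sprintf("data-version: synthetic/seed%d", seed),
           "ontology: hp-fixture", "",
           "[Term]", paste0("id: ", root_id),
           "name: Phenotypic abnormality", "")
  for (i in seq_len(n_body)) {
    parent <- if (i == 1) root_id else
      sample(c(root_id, ids[seq_len(i - 1L)]), 1L)
    stanza <- c("[Term]", paste0("id: ", ids[i]),
                paste0("name: ", picks[[i]]$name))
    for (s in picks[[i]]$syn) {
      stanza <- c(stanza, sprintf("synonym: \"%s\" EXACT []", s))
    }
    stanza <- c(stanza, paste0("is_a: ", parent, " ! parent"), "")
    out <- c(out, stanza)
  }
  out <- c(out, "[Term]", sprintf("id: HP:%07d", 200L + n_body + 1L),
           "name: obsolete Clinical finding variant",
           "is_obsolete: true", paste0("replaced_by: ", root_id), "")
  paste0(paste(out, collapse = "\n"), "\n")
}

#' Generator configuration
#'
#' Defaults reproduce the benchmark dataset's per-report medians: 15 PHI,
#' 3 abbreviations and 7 HPO terms per report over 50 reports. PHI are
#' split across person/date/location channels in the proportions the
#' benchmark observed (166 : 231 : 51).
#'
#' @param seed Integer seed; identical seed and config give an identical
#'   corpus.
#' @param n_reports Number of reports.
#' @param language `"en"` or `"fr"` (the fr-like mode drives the glossary
#'   translation engine).
#' @param phi_per_report,abbrev_per_report,hpo_per_report Planted counts.
#' @param frac_negated,frac_family Fractions of HPO phrases in negated /
#'   family-member context.
#' @param frac_measurement Fraction of affirmed HPO phrases carrying a
#'   measurement.
#' @param frac_probe Probability of one descriptive-syndrome sentence per
#'   report (a designed false-positive probe: its term is recorded
#'   separately in the gold, not as an expected hit).
#' @param frac_eponym Probability of one allowlisted-eponym sentence per
#'   report (a designed over-redaction probe).
#' @param filler_range Integer range of non-informative filler sentences.
#' @return Object of class `ptx_gencfg`.
#' @export
generator_config <- function(seed = 1L, n_reports = 50L, language = "en",
                             phi_per_report = 15L, abbrev_per_report = 3L,
                             hpo_per_report = 7L, frac_negated = 0.2,
                             frac_family = 0.15, frac_measurement = 0.3,
                             frac_probe = 0.1, frac_eponym = 0.2,
                             filler_range = c(2L, 4L)) {
  fr <- c(frac_negated, frac_family, frac_measurement, frac_probe,
          frac_eponym)
  if (any(fr < 0 | fr > 1)) stop("fractions must lie in [0, 1]")
  if (frac_negated + frac_family > 1) {
    stop("frac_negated + frac_family must not exceed 1")
  }
  if (n_reports < 1 || phi_per_report < 0 || abbrev_per_report < 0 ||
      hpo_per_report < 0) {
    stop("counts must be non-negative (n_reports positive)")
  }
  language <- match.arg(language, c("en", "fr"))
  n_neg <- round_half_up(frac_negated * hpo_per_report)
  n_fam <- round_half_up(frac_family * hpo_per_report)
  if (n_neg + n_fam > hpo_per_report) {
    stop("negated/family fractions unsatisfiable for hpo_per_report")
  }
  structure(list(seed = as.integer(seed), n_reports = as.integer(n_reports),
                 language = language,
                 phi_per_report = as.integer(phi_per_report),
                 abbrev_per_report = as.integer(abbrev_per_report),
                 hpo_per_report = as.integer(hpo_per_report),
                 frac_negated = frac_negated, frac_family = frac_family,
                 frac_measurement = frac_measurement,
                 frac_probe = frac_probe, frac_eponym = frac_eponym,
                 filler_range = as.integer(filler_range)),
            class = "ptx_gencfg")
}

.measures <- c("-2.5 SD", "+2 SD", "48 cm", "3rd percentile",
               "97th percentile", "52 cm", "-3 SD", "12 kg")

# One sentence assembled from literal parts and annotated slots.
# Returns list(text, phi, hpo, abbrev, probe) with sentence-local offsets.
.slot_sentence <- function(parts) {
  text <- ""
  phi <- data.frame(start = integer(0), end = integer(0),
                    category = character(0), surface = character(0),
                    stringsAsFactors = FALSE)
  abbrev <- data.frame(start = integer(0), end = integer(0),
                       stringsAsFactors = FALSE)
  for (p in parts) {
    at <- nchar(text)
    text <- paste0(text, p$text)
    if (!is.null(p$phi)) {
      phi <- rbind(phi, data.frame(start = at, end = at + nchar(p$text),
                                   category = p$phi, surface = p$text,
                                   stringsAsFactors = FALSE))
    }
    if (isTRUE(p$abbrev)) {
      abbrev <- rbind(abbrev, data.frame(start = at,
                                         end = at + nchar(p$text)))
    }
  }
  list(text = text, phi = phi, abbrev = abbrev)
}

.lit <- function(x) list(text = x)
.phi <- function(x, cat) list(text = x, phi = cat)
.abb <- function(x) list(text = x, abbrev = TRUE)

# Sentence templates. Each builder returns a .slot_sentence() result.
.tpl_person <- function(name, k, lang) {
  if (lang == "fr") {
    tps <- list(
      list(.lit("Vu par Dr "), .phi(name, "PERSON"), .lit(".")),
      list(.lit("La mère, née "), .phi(name, "PERSON"),
           .lit(", a été vue.")),
      list(.lit("Adressé par Dr "), .phi(name, "PERSON"), .lit("."))
    )
  } else {
    tps <- list(
      list(.lit("Mr "), .phi(name, "PERSON"),
           .lit(" attended the consultation.")),
      list(.lit("Mrs "), .phi(name, "PERSON"),
           .lit(" described the early history.")),
      list(.lit("The patient was examined by Dr "), .phi(name, "PERSON"),
           .lit(".")),
      list(.lit("The mother, née "), .phi(name, "PERSON"),
           .lit(", is in good health.")),
      list(.lit("The file was reviewed by Dr "), .phi(name, "PERSON"),
           .lit("."))
    )
  }
  .slot_sentence(tps[[(k - 1L) %% length(tps) + 1L]])
}

.tpl_date <- function(date, k, lang) {
  if (identical(date$kind, "year")) {
    parts <- if (lang == "fr") {
      list(.lit("Né en "), .phi(date$text, "DATE_TIME"), .lit("."))
    } else {
      list(.lit("The child was born in "), .phi(date$text, "DATE_TIME"),
           .lit("."))
    }
    return(.slot_sentence(parts))
  }
  if (lang == "fr") {
    tps <- list(
      list(.lit("Examen le "), .phi(date$text, "DATE_TIME"), .lit(".")),
      list(.lit("Revu le "), .phi(date$text, "DATE_TIME"), .lit("."))
    )
  } else {
    tps <- list(
      list(.lit("The patient was seen on "), .phi(date$text, "DATE_TIME"),
           .lit(".")),
      list(.lit("Review took place on "), .phi(date$text, "DATE_TIME"),
           .lit(".")),
      list(.lit("An assessment was scheduled for "),
           .phi(date$text, "DATE_TIME"), .lit("."))
    )
  }
  .slot_sentence(tps[[(k - 1L) %% length(tps) + 1L]])
}

.tpl_location <- function(loc, k, lang) {
  if (lang == "fr") {
    tps <- list(
      list(.lit("La famille habite à "), .phi(loc, "LOCATION"),
           .lit(".")))
  } else {
    tps <- list(
      list(.lit("The family lives in "), .phi(loc, "LOCATION"), .lit(".")),
      list(.lit("The patient was referred from "), .phi(loc, "LOCATION"),
           .lit(".")))
  }
  .slot_sentence(tps[[(k - 1L) %% length(tps) + 1L]])
}

.tpl_abbrev <- function(key, lang) {
  if (lang == "fr") {
    .slot_sentence(list(.abb(key), .lit(" était noté.")))
  } else {
    .slot_sentence(list(.abb(key), .lit(" was noted during follow-up.")))
  }
}

.tpl_hpo <- function(label, reason, measure, k, lang) {
  lab <- .lit(label)
  if (lang == "fr") {
    parts <- switch(reason,
      affirmed = if (is.na(measure)) {
        list(.lit("Le patient présente "), lab, .lit("."))
      } else {
        list(.lit("Le patient présente "), lab,
             .lit(paste0(" à ", measure, ".")))
      },
      negated = list(.lit("Pas de "), lab, .lit(" observée.")),
      family = list(.lit("La mère présente "), lab, .lit("."))
    )
    return(.slot_sentence(parts))
  }
  parts <- switch(reason,
    affirmed = {
      tps <- list(
        list(.lit("The patient has "), lab, .lit(".")),
        list(.lit("Examination revealed "), lab, .lit(".")),
        list(.lit("He presented with "), lab, .lit(".")),
        list(.lit("Clinical review showed "), lab, .lit("."))
      )
      p <- tps[[(k - 1L) %% length(tps) + 1L]]
      if (!is.na(measure)) {
        p[[length(p)]] <- .lit(paste0(" at ", measure, "."))
      }
      p
    },
    negated = {
      tps <- list(
        list(.lit("There is no "), lab, .lit(".")),
        list(.lit("No "), lab, .lit(" was observed.")),
        list(.lit("The patient has never had "), lab, .lit(".")),
        list(.lit("Absence of "), lab, .lit(" was confirmed."))
      )
      tps[[(k - 1L) %% length(tps) + 1L]]
    },
    family = {
      tps <- list(
        list(.lit("His mother has "), lab, .lit(".")),
        list(.lit("There is a family history of "), lab, .lit(".")),
        list(.lit("Her brother presented with "), lab, .lit("."))
      )
      tps[[(k - 1L) %% length(tps) + 1L]]
    })
  .slot_sentence(parts)
}

.tpl_probe <- function(label, lang) {
  if (lang == "fr") {
    .slot_sentence(list(.lit("Ce syndrome est associé avec "),
                        .lit(label), .lit(".")))
  } else {
    .slot_sentence(list(.lit("This syndrome is typically associated with "),
                        .lit(label), .lit(".")))
  }
}

.tpl_eponym <- function(eponym, lang) {
  if (lang == "fr") {
    .slot_sentence(list(.lit("Décrit par Dr "), .lit(eponym),
                        .lit(".")))
  } else {
    .slot_sentence(list(.lit("The phenotype matches the description by Dr "),
                        .lit(eponym), .lit(".")))
  }
}

.fillers_en <- c("Follow-up was planned.", "Routine monitoring continued.",
                 "Vaccinations are up to date.",
                 "The consultation went well.",
                 "School attendance is regular.")
.fillers_fr <- c("Le suivi était prévu.")

.random_date <- function() {
  kinds <- c("dmy_slash", "dmy_dot", "iso", "monthname", "year")
  kind <- sample(kinds, 1L)
  d <- sample(1:28, 1L); m <- sample(1:12, 1L); y <- sample(2015:2023, 1L)
  text <- switch(kind,
    dmy_slash = sprintf("%02d/%02d/%d", d, m, y),
    dmy_dot = sprintf("%02d.%02d.%d", d, m, y),
    iso = sprintf("%d-%02d-%02d", y, m, d),
    monthname = paste(d, c("January", "February", "March", "April", "May",
                           "June", "July", "August", "September", "October",
                           "November", "December")[m], y),
    year = as.character(y))
  list(kind = if (kind == "year") "year" else "date", text = text)
}

#' Generate a synthetic corpus with gold annotations
#'
#' Assembles templated reports: PHI slots filled from the generator's name,
#' location and date pools (the same pools exported as detector gazetteers
#' by [synth_lexicons()]), HPO slots filled with term names or synonyms in
#' affirmed / negated / family templates, abbreviations, measurements, and
#' two designed probe families (descriptive-syndrome sentences and
#' allowlisted-eponym sentences). Gold spans index into the emitted report
#' text. Deterministic per `cfg$seed`.
#'
#' @param cfg A `ptx_gencfg` from [generator_config()].
#' @param ontology A `ptx_ontology` (normally from [make_fixture_ontology()]).
#' @param lexicons Lexicon bundle from [synth_lexicons()].
#' @return Object of class `ptx_corpus`: list of reports, each
#'   `list(doc_id, text, gold)` where gold holds `phi_spans` (data frame
#'   `start`, `end`, `category`, `surface`), `hpo_terms` (data frame
#'   `term_id`, `confidence`, `reason`), `abbreviation_sites` (data frame of
#'   spans) and `probe_terms` (character vector of planted-but-unexpected
#'   term ids).
#' @export
generate_corpus <- function(cfg, ontology, lexicons = synth_lexicons()) {
  stopifnot(inherits(cfg, "ptx_gencfg"), inherits(ontology, "ptx_ontology"))
  set.seed(cfg$seed)
  lang <- cfg$language
  active <- Filter(function(t) !t$obsolete && t$name != "Phenotypic abnormality",
                   ontology)
  by_name <- stats::setNames(vapply(active, function(t) t$id, character(1)),
                             vapply(active, function(t) t$name, character(1)))
  pool_by_name <- stats::setNames(.phenotype_pool,
                                  vapply(.phenotype_pool, `[[`, character(1),
                                         "name"))
  # a label the generator can plant for each term, per language
  plantable <- Filter(function(nm) {
    if (lang == "en") TRUE
    else !is.null(pool_by_name[[nm]]$fr)
  }, names(by_name))
  abbrev_term_ids <- stats::setNames(by_name[.synth_abbrev_term],
                                     names(.synth_abbrev_term))
  n_needed <- cfg$hpo_per_report + 1L # +1 for a possible probe
  if (length(plantable) < n_needed) {
    stop("ontology too small for hpo_per_report (need ", n_needed,
         " plantable terms, have ", length(plantable), ")")
  }
  # PHI channel split in the benchmark's observed proportions
  n_pers <- round_half_up(cfg$phi_per_report * 166 / 449)
  n_date <- round_half_up(cfg$phi_per_report * 231 / 449)
  n_loc <- cfg$phi_per_report - n_pers - n_date
  n_neg <- round_half_up(cfg$frac_negated * cfg$hpo_per_report)
  n_fam <- round_half_up(cfg$frac_family * cfg$hpo_per_report)

  reports <- vector("list", cfg$n_reports)
  for (r in seq_len(cfg$n_reports)) {
    sents <- list()
    add <- function(s, hpo = NULL, probe = NA_character_) {
      sents[[length(sents) + 1L]] <<- list(s = s, hpo = hpo, probe = probe)
    }
    for (k in seq_len(n_pers)) {
      add(.tpl_person(sample(lexicons$name_pool, 1L), sample.int(9L, 1L),
                      lang))
    }
    for (k in seq_len(n_date)) {
      add(.tpl_date(.random_date(), sample.int(9L, 1L), lang))
    }
    for (k in seq_len(n_loc)) {
      add(.tpl_location(sample(lexicons$location_pool, 1L),
                        sample.int(9L, 1L), lang))
    }
    # abbreviations; term-linked ones also carry a gold phenotype
    keys <- sample(names(lexicons$abbrev$entries),
                   min(cfg$abbrev_per_report,
                       length(lexicons$abbrev$entries)))
    used_terms <- character(0)
    for (k in keys) {
      linked <- if (k %in% names(.synth_abbrev_term) &&
                    !is.na(abbrev_term_ids[[k]])) {
        abbrev_term_ids[[k]]
      } else NA_character_
      hpo <- if (!is.na(linked)) {
        used_terms <- c(used_terms, linked)
        data.frame(term_id = linked, confidence = "high",
                   reason = "affirmed", stringsAsFactors = FALSE)
      } else NULL
      add(.tpl_abbrev(k, lang), hpo = hpo)
    }
    # phenotype sentences: counts include the term-linked abbreviations
    n_linked <- length(used_terms)
    n_sent_hpo <- max(0L, cfg$hpo_per_report - n_linked)
    n_neg_r <- min(n_neg, n_sent_hpo)
    n_fam_r <- min(n_fam, n_sent_hpo - n_neg_r)
    n_aff_r <- n_sent_hpo - n_neg_r - n_fam_r
    avail <- setdiff(plantable, names(by_name)[by_name %in% used_terms])
    chosen <- sample(avail, n_sent_hpo + 1L) # last one reserved for probe
    reasons <- c(rep("affirmed", n_aff_r), rep("negated", n_neg_r),
                 rep("family", n_fam_r))
    for (i in seq_len(n_sent_hpo)) {
      nm <- chosen[i]
      label <- if (lang == "fr") pool_by_name[[nm]]$fr else {
        syns <- pool_by_name[[nm]]$syn
        if (length(syns) && stats::runif(1) < 0.4) sample(c(syns), 1L)
        else nm
      }
      measure <- if (reasons[i] == "affirmed" &&
                     stats::runif(1) < cfg$frac_measurement) {
        sample(.measures, 1L)
      } else NA_character_
      add(.tpl_hpo(label, reasons[i], measure, sample.int(9L, 1L), lang),
          hpo = data.frame(
            term_id = unname(by_name[nm]),
            confidence = if (reasons[i] == "affirmed") "high" else "low",
            reason = reasons[i], stringsAsFactors = FALSE))
    }
    if (stats::runif(1) < cfg$frac_probe) {
      nm <- chosen[n_sent_hpo + 1L]
      label <- if (lang == "fr") pool_by_name[[nm]]$fr else nm
      add(.tpl_probe(label, lang), probe = unname(by_name[nm]))
    }
    if (stats::runif(1) < cfg$frac_eponym) {
      add(.tpl_eponym(sample(setdiff(.synth_eponyms, "Iso Kikuchi"), 1L),
                      lang))
    }
    fillers <- if (lang == "fr") .fillers_fr else .fillers_en
    n_fill <- sample(seq(cfg$filler_range[1], cfg$filler_range[2]), 1L)
    for (k in seq_len(n_fill)) {
      add(.slot_sentence(list(.lit(sample(fillers, 1L)))))
    }
    sents <- sents[sample.int(length(sents))]
    # assemble text and absolute gold offsets
    text <- ""
    phi <- data.frame(start = integer(0), end = integer(0),
                      category = character(0), surface = character(0),
                      stringsAsFactors = FALSE)
    abbrev_sites <- data.frame(start = integer(0), end = integer(0))
    hpo <- data.frame(term_id = character(0), confidence = character(0),
                      reason = character(0), stringsAsFactors = FALSE)
    probes <- character(0)
    for (it in sents) {
      base <- nchar(text) + if (nzchar(text)) 1L else 0L
      text <- if (nzchar(text)) paste(text, it$s$text) else it$s$text
      if (nrow(it$s$phi)) {
        ph <- it$s$phi
        ph$start <- ph$start + base
        ph$end <- ph$end + base
        phi <- rbind(phi, ph)
      }
      if (nrow(it$s$abbrev)) {
        ab <- it$s$abbrev
        ab$start <- ab$start + base
        ab$end <- ab$end + base
        abbrev_sites <- rbind(abbrev_sites, ab)
      }
      if (!is.null(it$hpo)) hpo <- rbind(hpo, it$hpo)
      if (!is.na(it$probe)) probes <- c(probes, it$probe)
    }
    phi <- phi[order(phi$start), , drop = FALSE]
    rownames(phi) <- NULL
    reports[[r]] <- list(
      doc_id = sprintf("report_%03d", r), text = text,
      gold = list(phi_spans = phi, hpo_terms = hpo,
                  abbreviation_sites = abbrev_sites,
                  probe_terms = probes))
  }
  structure(list(reports = reports, cfg = cfg), class = "ptx_corpus")
}

#' @export
print.ptx_corpus <- function(x, ...) {
  cat(sprintf("<ptx_corpus> %d reports (language %s, seed %d)\n",
              length(x$reports), x$cfg$language, x$cfg$seed))
  invisible(x)
}

#' Write a corpus, its gold annotations and fixtures to disk
#'
#' Emits one `.txt` per report, one gold `.tsv` per report (schema
#' `doc_id`, `kind`, `start`, `end`, `category_or_term_id`), the fixture
#' ontology and the lexicon TSVs, under a seed-named directory.
#'
#' @param corpus A `ptx_corpus`.
#' @param dir Output directory (created if needed).
#' @param obo_text Fixture ontology text to write alongside (optional).
#' @return The directory path, invisibly.
#' @export
write_corpus <- function(corpus, dir, obo_text = NULL) {
  stopifnot(inherits(corpus, "ptx_corpus"))
  out <- file.path(dir, sprintf("corpus_seed%d", corpus$cfg$seed))
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  for (rep in corpus$reports) {
    writeLines(rep$text, file.path(out, paste0(rep$doc_id, ".txt")),
               useBytes = TRUE)
    g <- rep$gold
    rows <- rbind(
      if (nrow(g$phi_spans)) data.frame(
        doc_id = rep$doc_id, kind = "phi", start = g$phi_spans$start,
        end = g$phi_spans$end, category_or_term_id = g$phi_spans$category,
        stringsAsFactors = FALSE),
      if (nrow(g$hpo_terms)) data.frame(
        doc_id = rep$doc_id, kind = "hpo", start = NA_integer_,
        end = NA_integer_, category_or_term_id = g$hpo_terms$term_id,
        stringsAsFactors = FALSE))
    if (is.null(rows)) {
      rows <- data.frame(doc_id = character(0), kind = character(0),
                         start = integer(0), end = integer(0),
                         category_or_term_id = character(0))
    }
    utils::write.table(rows, file.path(out, paste0(rep$doc_id, ".gold.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE,
                       fileEncoding = "UTF-8")
  }
  if (!is.null(obo_text)) {
    writeLines(obo_text, file.path(out, "fixture.obo"), useBytes = TRUE,
               sep = "")
  }
  invisible(out)
}
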