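# Pipeline step (ii): translation behind an engine contract. Real neural
# machine translation plugs in through the same interface; the package ships
# two deterministic engines (passthrough and glossary word-substitution) so
# every downstream stage is testable offline.

#' Construct a translation engine
#'
#' @param name Engine name.
#' @param source_language ISO 639-1 code the engine accepts.
#' @param translate Function mapping one sentence string to one English
#'   sentence string; must be deterministic and return non-empty output for
#'   non-empty input.
#' @return Object of class `ptx_engine`.
#' @export
translation_engine <- function(name, source_language, translate) {
  stopifnot(is.function(translate))
  structure(list(name = name, source_language = source_language,
                 translate = translate),
            class = "ptx_engine")
}

#' Passthrough engine (identity translation)
#'
#' @param source_language Language code the engine claims to accept.
#' @return A `ptx_engine` returning its input unchanged.
#' @export
make_passthrough_engine <- function(source_language = "en") {
  translation_engine("passthrough", source_language, function(s) s)
}

#' Glossary engine (deterministic word substitution)
#'
#' Replaces whole-token occurrences of glossary keys by their English
#' equivalents, leaving all other tokens byte-identical. Serves as an
#' offline, deterministic stand-in for a sentence-level translator.
#'
#' @param glossary Named character vector, source word -> English word.
#' @param source_language Source language code.
#' @return A `ptx_engine` (subclass `ptx_glossary_engine`).
#' @export
make_glossary_engine <- function(glossary, source_language = "fr") {
  if (anyDuplicated(names(glossary))) stop("glossary keys must be unique")
  d <- if (length(glossary)) {
    abbreviation_dictionary(glossary, language = source_language)
  } else NULL
  eng <- translation_engine(
    "glossary", source_language,
    function(s) if (is.null(d)) s else expand_abbreviations(s, d)$text)
  eng$glossary <- d
  class(eng) <- c("ptx_glossary_engine", class(eng))
  eng
}

#' Translate a document sentence-by-sentence
#'
#' Applies the engine to each sentence, preserving sentence count and the
#' text between sentences. The output document is at stage `"translated"`
#' with language `"en"`. An edit map into the input text is attached so
#' annotation spans can be remapped: glossary engines yield token-level
#' edits; arbitrary engines yield one edit per changed sentence.
#'
#' @param doc A `ptx_document` at stage `"expanded"` (or `"raw"`).
#' @param engine A `ptx_engine` whose `source_language` matches the
#'   document's language.
#' @return The translated `ptx_document`; the edit map is in
#'   `attr(, "edits")`.
#' @export
translate_document <- function(doc, engine) {
  stopifnot(inherits(doc, "ptx_document"), inherits(engine, "ptx_engine"))
  if (!identical(doc$language, engine$source_language)) {
    stop(sprintf("language mismatch: document is '%s', engine accepts '%s'",
                 doc$language, engine$source_language))
  }
  if (inherits(engine, "ptx_glossary_engine")) {
    # token-level substitution commutes with sentence segmentation, so run
    # it once over the whole text and keep fine-grained edits
    res <- if (is.null(engine$glossary)) list(text = doc$text, edits =
      data.frame(start = integer(0), end = integer(0),
                 original = character(0), replacement = character(0),
                 stringsAsFactors = FALSE))
      else expand_abbreviations(doc$text, engine$glossary)
    out <- doc
    out$text <- res$text
    out$language <- "en"
    out$stage <- "translated"
    out$sentences <- NULL
    attr(out, "edits") <- res$edits
    return(out)
  }
  spans <- segment_sentences(doc$text)
  edits <- data.frame(start = integer(0), end = integer(0),
                      original = character(0), replacement = character(0),
                      stringsAsFactors = FALSE)
  for (i in seq_len(nrow(spans))) {
    src <- substring(doc$text, spans$start[i] + 1L, spans$end[i])
    dst <- tryCatch(engine$translate(src), error = function(e) {
      stop(sprintf("translation engine '%s' failed on sentence %d: %s",
                   engine$name, i, conditionMessage(e)))
    })
    if (nzchar(src) && !nzchar(dst)) {
      stop(sprintf("engine '%s' returned empty output for sentence %d",
                   engine$name, i))
    }
    if (!identical(src, dst)) {
      edits <- rbind(edits, data.frame(
        start = spans$start[i], end = spans$end[i],
        original = src, replacement = dst, stringsAsFactors = FALSE))
    }
  }
  out <- doc
  out$text <- apply_edits(doc$text, edits)
  out$language <- "en"
  out$stage <- "translated"
  out$sentences <- NULL
  attr(out, "edits") <- edits
  out
}
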