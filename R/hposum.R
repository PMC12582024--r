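# Pipeline step (iv): sentence-level HPO concept recognition by lemmatized
# token-subset matching, confidence flags from negation and family cues,
# and capture of quantitative evidence.

#' Default negation and family-member cue lists
#'
#' Cue matching operates on the lemmatized token sequence of a sentence, so
#' each cue is stored in lemma form. The two sets are disjoint.
#'
#' @return Object of class `ptx_cues` with `negation` and `family`
#'   character vectors (single tokens or multi-token phrases).
#' @export
default_cues <- function() {
  cue_lists(
    negation = c("no", "not", "without", "never", "absence of", "absent",
                 "deny", "neither", "nor", "free of", "negative for"),
    family = c("mother", "father", "brother", "sister", "aunt", "uncle",
               "grandmother", "grandfather", "cousin", "sibling",
               "maternal", "paternal", "family history")
  )
}

#' Construct cue lists
#'
#' @param negation Character vector of negation cues (lemma form).
#' @param family Character vector of family-member cues (lemma form).
#' @return Object of class `ptx_cues`.
#' @export
cue_lists <- function(negation, family) {
  negation <- unique(normalize_key(negation))
  family <- unique(normalize_key(family))
  if (!length(negation) || !length(family)) {
    stop("cue sets must be non-empty")
  }
  if (length(intersect(negation, family))) {
    stop("negation and family cue sets must be disjoint")
  }
  structure(list(negation = negation, family = family), class = "ptx_cues")
}

# Lemma sequence of a sentence as one space-delimited string, placeholders
# and empty lemmas dropped; used for whole-phrase cue search.
sentence_lemma_string <- function(sentence) {
  lem <- sentence$lemmas
  paste(lem[nzchar(lem)], collapse = " ")
}

cue_present <- function(sentence, cues) {
  hay <- paste0(" ", sentence_lemma_string(sentence), " ")
  any(vapply(cues, function(cu) {
    grepl(paste0(" ", cu, " "), hay, fixed = TRUE)
  }, logical(1)))
}

#' Detect negation in a sentence
#'
#' Scope is the whole sentence: returns `TRUE` iff any negation cue occurs
#' anywhere in the sentence's lemma sequence.
#'
#' @param sentence An annotated sentence (from [annotate_document()]).
#' @param cues A `ptx_cues` object.
#' @return Logical scalar.
#' @export
detect_negation <- function(sentence, cues = default_cues()) {
  cue_present(sentence, cues$negation)
}

#' Detect family-member context in a sentence
#'
#' @inheritParams detect_negation
#' @return Logical scalar.
#' @export
detect_family <- function(sentence, cues = default_cues()) {
  cue_present(sentence, cues$family)
}

#' Match ontology terms in a sentence
#'
#' A term matches iff the normalized token set of one of its labels (name or
#' synonym) is a subset of the sentence's lemma set (stopwords excluded).
#' `matched_text` is the minimal sentence substring covering the source
#' tokens of the matched lemmas.
#'
#' @param sentence An annotated sentence whose lemmas were computed with the
#'   same normalizer as the index.
#' @param index A `ptx_index` from [build_synonym_index()].
#' @param text The document text the sentence's token spans index into.
#' @return Data frame with columns `term_id`, `label`, `matched_label`,
#'   `matched_text`, `start` (document offset of the earliest matched
#'   token).
#' @export
match_sentence <- function(sentence, index, text) {
  empty <- data.frame(term_id = character(0), label = character(0),
                      matched_label = character(0),
                      matched_text = character(0), start = integer(0),
                      stringsAsFactors = FALSE)
  lem <- sentence$lemmas
  lemma_set <- setdiff(unique(lem[nzchar(lem)]), index$stopwords)
  if (!length(lemma_set)) return(empty)
  out <- empty
  for (tid in names(index$term_token_sets)) {
    for (ts in index$term_token_sets[[tid]]) {
      if (all(ts$tokens %in% lemma_set)) {
        pos <- which(lem %in% ts$tokens)
        s <- min(sentence$tokens$start[pos])
        e <- max(sentence$tokens$end[pos])
        out <- rbind(out, data.frame(
          term_id = tid, label = unname(index$labels[tid]),
          matched_label = ts$label,
          matched_text = substring(text, s + 1L, e),
          start = s, stringsAsFactors = FALSE))
        break # one match per term per sentence suffices
      }
    }
  }
  out
}

.measure_re <- paste0(
  "[-+]?\\d+(?:[.,]\\d+)?\\s?(?:SD|DS)\\b",
  "|\\d+(?:st|nd|rd|th|e)?\\s?(?:percentile|centile)\\b",
  "|[-+]?\\d+(?:[.,]\\d+)?\\s?(?:cm|mm|kg|g|%)(?![[:alpha:]])")

#' Extract the quantitative expression nearest a matched term
#'
#' Finds measurement expressions in the sentence (number with unit,
#' percentile, or standard-deviation notation such as `-2.5 SD`,
#' `3rd percentile`, `48 cm`) and returns the one with the smallest token
#' distance to the matched text, or `NA` if the sentence has none.
#'
#' @param sentence An annotated sentence.
#' @param text Document text.
#' @param match_start,match_end Document offsets of the matched text.
#' @return Character scalar (the measurement expression) or `NA_character_`.
#' @export
extract_quantitative <- function(sentence, text, match_start, match_end) {
  s <- sentence$span[["start"]]
  e <- sentence$span[["end"]]
  sent_text <- substring(text, s + 1L, e)
  m <- gregexpr(.measure_re, sent_text, perl = TRUE)[[1]]
  if (m[1] == -1) return(NA_character_)
  st <- as.integer(m) - 1L + s
  len <- attr(m, "match.length")
  en <- st + len
  # token distance: number of tokens lying strictly between the two spans
  dist <- vapply(seq_along(st), function(i) {
    if (en[i] > match_start && match_end > st[i]) return(0L)
    lo <- min(en[i], match_end)
    hi <- max(st[i], match_start)
    sum(sentence$tokens$start >= lo & sentence$tokens$end <= hi)
  }, integer(1))
  best <- which.min(dist) # ties: earliest measurement wins (which.min)
  trimws(substring(text, st[best] + 1L, en[best]))
}

#' Summarize a document into phenotype hits
#'
#' Per sentence, matches ontology terms and classifies the sentence:
#' family cue present -> `family`; else negation cue present -> `negated`;
#' else `affirmed`. Per term across sentences one hit is emitted:
#' confidence is `high` iff any affirmed occurrence exists (reason
#' `affirmed`), otherwise `low` with the reason of the earliest occurrence.
#' Hits are sorted by first occurrence offset.
#'
#' @param doc A `ptx_document` (annotated or not; annotation is computed on
#'   demand) at stage `translated` or `deidentified`.
#' @param index A `ptx_index`.
#' @param cues A `ptx_cues` object.
#' @return Data frame of class `ptx_hits` with columns `term_id`, `label`,
#'   `confidence`, `reason`, `evidence_sentence` (1-based index of the
#'   earliest matching sentence), `matched_text`, `quantitative`, `count`,
#'   `first_offset`.
#' @export
summarize_document <- function(doc, index, cues = default_cues()) {
  stopifnot(inherits(doc, "ptx_document"), inherits(index, "ptx_index"))
  if (is.null(doc$sentences)) {
    doc <- annotate_document(doc, lemmatizer = index$lemmatizer)
  }
  empty <- data.frame(term_id = character(0), label = character(0),
                      confidence = character(0), reason = character(0),
                      evidence_sentence = integer(0),
                      matched_text = character(0),
                      quantitative = character(0), count = integer(0),
                      first_offset = integer(0), stringsAsFactors = FALSE)
  occ <- list()
  for (si in seq_along(doc$sentences)) {
    sent <- doc$sentences[[si]]
    hits <- match_sentence(sent, index, doc$text)
    if (!nrow(hits)) next
    reason <- if (detect_family(sent, cues)) "family"
              else if (detect_negation(sent, cues)) "negated"
              else "affirmed"
    for (i in seq_len(nrow(hits))) {
      q <- extract_quantitative(sent, doc$text, hits$start[i],
                                hits$start[i] + nchar(hits$matched_text[i]))
      occ[[length(occ) + 1L]] <- data.frame(
        term_id = hits$term_id[i], label = hits$label[i],
        reason = reason, sentence = si,
        matched_text = hits$matched_text[i], quantitative = q,
        start = hits$start[i], stringsAsFactors = FALSE)
    }
  }
  if (!length(occ)) return(structure(empty, class = c("ptx_hits",
                                                      class(empty))))
  occ <- do.call(rbind, occ)
  out <- lapply(split(occ, occ$term_id), function(o) {
    o <- o[order(o$start), , drop = FALSE]
    affirmed <- any(o$reason == "affirmed")
    reason <- if (affirmed) "affirmed" else o$reason[1]
    quant <- o$quantitative[!is.na(o$quantitative)]
    data.frame(
      term_id = o$term_id[1], label = o$label[1],
      confidence = if (affirmed) "high" else "low",
      reason = reason, evidence_sentence = o$sentence[1],
      matched_text = o$matched_text[1],
      quantitative = if (length(quant)) quant[1] else NA_character_,
      count = nrow(o), first_offset = o$start[1],
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out <- out[order(out$first_offset, out$term_id), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("ptx_hits", class(out)))
}
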