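# Pipeline step (i): sentence segmentation, tokenization and abbreviation
# expansion. Documents carry 0-based half-open character spans through every
# stage; transforming stages return edit maps so spans can be remapped.

#' Create a document
#'
#' @param text Report text (UTF-8).
#' @param doc_id Identifier string.
#' @param language ISO 639-1 code of the source language.
#' @param stage Processing stage label.
#' @return Object of class `ptx_document`.
#' @export
document <- function(text, doc_id = "doc", language = "en",
                     stage = c("raw", "expanded", "translated",
                               "deidentified")) {
  stage <- match.arg(stage)
  structure(list(doc_id = doc_id, language = language, text = text,
                 sentences = NULL, stage = stage),
            class = "ptx_document")
}

#' @export
print.ptx_document <- function(x, ...) {
  cat(sprintf("<ptx_document> %s [%s, stage=%s] %d chars, %s sentences\n",
              x$doc_id, x$language, x$stage, nchar(x$text),
              if (is.null(x$sentences)) "unsegmented" else
                length(x$sentences)))
  invisible(x)
}

#' Segment text into sentence spans
#'
#' Sentences end at `.`, `!`, `?` or a newline. A period does not terminate a
#' sentence when it sits between two digits (numeric dates such as
#' `12.03.2019` never split internally) or when it ends a token listed in
#' `protected` (known abbreviations carrying a period). Returned spans are
#' 0-based half-open intervals trimmed of surrounding whitespace; they are
#' sorted, non-overlapping and cover all non-whitespace text.
#'
#' @param text A single string.
#' @param protected Character vector of abbreviation tokens whose trailing
#'   period must not split (e.g. `"e.g"`).
#' @return Data frame with columns `start`, `end` (0-based, half-open).
#' @export
segment_sentences <- function(text, protected = character(0)) {
  empty <- data.frame(start = integer(0), end = integer(0))
  if (is.na(text) || !nzchar(text)) return(empty)
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  n <- length(chars)
  is_break <- logical(n)
  for (i in seq_len(n)) {
    ch <- chars[i]
    if (ch == "\n") { is_break[i] <- TRUE; next }
    if (ch %in% c("!", "?")) { is_break[i] <- TRUE; next }
    if (ch == ".") {
      prev_digit <- i > 1 && grepl("[0-9]", chars[i - 1])
      next_digit <- i < n && grepl("[0-9]", chars[i + 1])
      if (prev_digit && next_digit) next
      # a sentence boundary needs whitespace (or end of text) after the dot
      if (i < n && !grepl("\\s", chars[i + 1])) next
      # a lowercase continuation signals an abbreviation, not a boundary
      rest <- sub("^\\s+", "", substring(text, i + 1L))
      if (nzchar(rest) && grepl("^[a-z]", rest)) next
      if (length(protected)) {
        before <- substr(text, max(1, i - 20), i - 1)
        tok <- sub(".*[^[:alnum:].]", "", before)
        if (tok %in% protected) next
      }
      is_break[i] <- TRUE
    }
  }
  bounds <- c(0L, which(is_break), n)
  spans <- empty
  for (k in seq_len(length(bounds) - 1L)) {
    s <- bounds[k]       # 0-based start (just after previous terminator)
    e <- bounds[k + 1L]  # includes the terminator character
    if (e <= s) next
    seg <- substring(text, s + 1L, e)
    lead <- nchar(seg) - nchar(sub("^\\s+", "", seg))
    trail <- nchar(seg) - nchar(sub("\\s+$", "", seg))
    s2 <- s + lead
    e2 <- e - trail
    if (e2 > s2) spans <- rbind(spans, data.frame(start = s2, end = e2))
  }
  rownames(spans) <- NULL
  spans
}

#' Expand abbreviations in text
#'
#' Replaces every whole-token occurrence of a dictionary key (case-sensitive
#' match on the stored key form) by its expansion, in a single pass:
#' expansions are not re-scanned. Where keys overlap at a position the
#' longest key wins.
#'
#' @param text A single string.
#' @param d A `ptx_abbrev` dictionary.
#' @return List with `text` (expanded string) and `edits`: a data frame
#'   (`start`, `end`, `original`, `replacement`) of 0-based half-open spans
#'   into the *input* text, sorted and non-overlapping. Applying the edits to
#'   the input reproduces the output exactly (see [apply_edits()]).
#' @export
expand_abbreviations <- function(text, d) {
  stopifnot(inherits(d, "ptx_abbrev"))
  no_edits <- data.frame(start = integer(0), end = integer(0),
                         original = character(0), replacement = character(0),
                         stringsAsFactors = FALSE)
  keys <- names(d$entries)
  if (!length(keys) || is.na(text) || !nzchar(text)) {
    return(list(text = text, edits = no_edits))
  }
  cand <- no_edits
  for (k in keys) {
    pat <- paste0("(?<![[:alnum:]])", escape_regex(k), "(?![[:alnum:]])")
    m <- gregexpr(pat, text, perl = TRUE)[[1]]
    if (m[1] == -1) next
    st <- as.integer(m) - 1L
    len <- attr(m, "match.length")
    cand <- rbind(cand, data.frame(
      start = st, end = st + len, original = k,
      replacement = unname(d$entries[k]), stringsAsFactors = FALSE))
  }
  if (!nrow(cand)) return(list(text = text, edits = no_edits))
  # longest key wins at a shared start; then drop overlaps left-to-right
  cand <- cand[order(cand$start, -nchar(cand$original)), , drop = FALSE]
  keep <- logical(nrow(cand))
  last_end <- -1L
  for (i in seq_len(nrow(cand))) {
    if (cand$start[i] >= last_end) {
      keep[i] <- TRUE
      last_end <- cand$end[i]
    }
  }
  edits <- cand[keep, , drop = FALSE]
  rownames(edits) <- NULL
  list(text = apply_edits(text, edits), edits = edits)
}

#' Apply an edit map to text
#'
#' @param text The original string the edits refer to.
#' @param edits Data frame (`start`, `end`, `replacement`), 0-based half-open
#'   spans, sorted, non-overlapping.
#' @return The edited string.
#' @export
apply_edits <- function(text, edits) {
  if (!nrow(edits)) return(text)
  out <- character(0)
  pos <- 0L
  for (i in seq_len(nrow(edits))) {
    out <- c(out, substring(text, pos + 1L, edits$start[i]),
             edits$replacement[i])
    pos <- edits$end[i]
  }
  paste0(paste(out, collapse = ""), substring(text, pos + 1L))
}

#' Remap character offsets through an edit map
#'
#' Maps 0-based offsets in the pre-edit text to offsets in the post-edit
#' text. Offsets inside an edited region clamp to the replacement's
#' boundaries (start-side for `side = "start"`, end-side for `side = "end"`),
#' so a span overlapping an edit maps to the smallest span covering the
#' replacement.
#'
#' @param offsets Integer vector of 0-based offsets.
#' @param edits Edit map as returned by [expand_abbreviations()].
#' @param side `"start"` or `"end"`.
#' @return Integer vector of remapped offsets.
#' @export
remap_offsets <- function(offsets, edits, side = c("start", "end")) {
  side <- match.arg(side)
  if (!nrow(edits)) return(offsets)
  deltas <- nchar(edits$replacement) - (edits$end - edits$start)
  vapply(offsets, function(o) {
    shift <- 0L
    for (i in seq_len(nrow(edits))) {
      if (edits$end[i] <= o) {
        shift <- shift + deltas[i]
      } else if (edits$start[i] < o) {
        # inside edit i
        if (side == "start") return(edits$start[i] + shift)
        return(edits$start[i] + shift + nchar(edits$replacement[i]))
      } else break
    }
    o + shift
  }, integer(1))
}

#' Remap spans through an edit map
#'
#' @param spans Data frame with `start`, `end` columns (0-based half-open).
#' @param edits Edit map.
#' @return `spans` with remapped `start`, `end`.
#' @export
remap_spans <- function(spans, edits) {
  if (!nrow(spans)) return(spans)
  spans$start <- remap_offsets(spans$start, edits, "start")
  spans$end <- remap_offsets(spans$end, edits, "end")
  spans
}

escape_regex <- function(x) gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", x)

#' Segment and annotate a document
#'
#' Computes sentence spans, per-sentence tokens with spans, and lemmas
#' aligned to tokens. Annotation is recomputed from the document's current
#' text, so it is valid for whatever stage the document is in.
#'
#' @param doc A `ptx_document`.
#' @param lemmatizer Token lemmatizer.
#' @param protected Protected abbreviation tokens for [segment_sentences()].
#' @return The document with `sentences` filled: a list of
#'   `list(span=, tokens=, lemmas=)`.
#' @export
annotate_document <- function(doc, lemmatizer = lemmatize_token,
                              protected = character(0)) {
  stopifnot(inherits(doc, "ptx_document"))
  spans <- segment_sentences(doc$text, protected)
  doc$sentences <- lapply(seq_len(nrow(spans)), function(i) {
    s <- spans$start[i]; e <- spans$end[i]
    sent_text <- substring(doc$text, s + 1L, e)
    tok <- tokenize(sent_text)
    if (nrow(tok)) {
      tok$start <- tok$start + s
      tok$end <- tok$end + s
    }
    list(span = c(start = s, end = e), tokens = tok,
         lemmas = token_lemmas(tok$surface, lemmatizer))
  })
  doc
}
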