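# Text normalization shared by the ontology index, the gazetteers and the
# sentence matcher. Everything funnels through one normalizer so that a label
# indexed from the ontology and a token seen in a report agree byte-for-byte.

# Length-preserving accent folding: every accented character maps to exactly
# one ASCII character, so character offsets computed on the folded text are
# valid in the original text. (A transliteration such as "œ" -> "oe"
# would break span arithmetic.)
.accent_from <- paste0(
  "àáâãäåç",
  "èéêëìíîï",
  "ñòóôõöùúûüýÿ",
  "ÀÁÂÃÄÅÇ",
  "ÈÉÊËÌÍÎÏ",
  "ÑÒÓÔÕÖÙÚÛÜÝ"
)
.accent_to <- paste0(
  "aaaaaac",
  "eeeeiiii",
  "noooooouuuuyy",
  "AAAAAAC",
  "EEEEIIII",
  "NOOOOOUUUUY"
)

#' Fold accents and case, preserving string length
#'
#' Maps accented Latin characters to their ASCII base character and lowercases
#' the result. The mapping is one-to-one per character, so offsets into the
#' folded string are valid offsets into the input.
#'
#' @param x Character vector.
#' @return Character vector of the same lengths as `x`.
#' @export
fold_text <- function(x) {
  tolower(chartr(.accent_from, .accent_to, x))
}

# Redaction placeholders ("<PERSON>", "<DATE_TIME>", ...) must never reach the
# concept matcher as ordinary words; this pattern identifies them wherever a
# normalizer or tokenizer needs to drop them.
.placeholder_re <- "<[A-Z_]+>"

# Irregular plurals and a few domain words the suffix rules would mangle.
.lemma_exceptions <- c(
  teeth = "tooth", feet = "foot", men = "man", women = "woman",
  children = "child", mice = "mouse", criteria = "criterion",
  foci = "focus", nuclei = "nucleus", vertebrae = "vertebra",
  diagnoses = "diagnosis", analyses = "analysis"
)

#' Lemmatize a single lowercase token
#'
#' Deterministic table + suffix-rule lemmatizer: irregular forms come from a
#' fixed exception table; regular plurals are reduced by English suffix rules
#' (`ies` -> `y`, `ches`/`shes`/`sses`/`xes`/`zes` -> drop `es`, final `s`
#' dropped unless the word ends in `ss`, `us` or `is`). Tokens of three or
#' fewer characters are returned unchanged.
#'
#' @param tok Character vector of lowercase tokens.
#' @return Character vector of lemmas.
#' @export
lemmatize_token <- function(tok) {
  vapply(tok, function(t) {
    if (!nzchar(t)) return(t)
    hit <- .lemma_exceptions[t]
    if (!is.na(hit)) return(unname(hit))
    n <- nchar(t)
    if (n <= 3) return(t)
    if (grepl("ies$", t) && n > 4) return(sub("ies$", "y", t))
    if (grepl("(ch|sh|ss|x|z)es$", t)) return(sub("es$", "", t))
    if (grepl("s$", t) && !grepl("(ss|us|is)$", t)) return(sub("s$", "", t))
    t
  }, character(1), USE.NAMES = FALSE)
}

#' Default stopword list for synonym indexing and matching
#'
#' A small fixed English list (articles, prepositions, copulas, possessives).
#' English is the pivot language of the pipeline, so one list suffices.
#'
#' @return Character vector of normalized stopword tokens.
#' @export
default_stopwords <- function() {
  c("a", "an", "the", "of", "in", "on", "at", "to", "and", "or",
    "with", "for", "by", "is", "are", "was", "were", "be", "been",
    "has", "have", "had", "this", "that", "his", "her", "their",
    "its", "as", "from")
}

#' Normalize a phrase into a token set
#'
#' Lowercases, folds accents, strips punctuation, tokenizes on non-alphanumeric
#' boundaries, lemmatizes each token, removes stopwords and collapses
#' duplicates. Redaction placeholders are discarded before tokenization so
#' they can never contribute lemmas. The result is returned sorted so equal
#' sets compare equal.
#'
#' @param text A single string (empty allowed).
#' @param stopwords Tokens to drop; defaults to [default_stopwords()].
#' @param lemmatizer Function mapping a character vector of lowercase tokens
#'   to lemmas; defaults to [lemmatize_token()].
#' @return Character vector: the normalized token set (possibly empty).
#' @export
normalize_phrase <- function(text, stopwords = default_stopwords(),
                             lemmatizer = lemmatize_token) {
  stopifnot(length(text) == 1L)
  if (is.na(text) || !nzchar(text)) return(character(0))
  text <- gsub(.placeholder_re, " ", text)
  folded <- fold_text(text)
  toks <- strsplit(gsub("[^a-z0-9]+", " ", folded), " ", fixed = TRUE)[[1]]
  toks <- toks[nzchar(toks)]
  if (!length(toks)) return(character(0))
  lem <- lemmatizer(toks)
  lem <- setdiff(unique(lem), stopwords)
  sort(lem)
}

# Normalized whole-phrase key used by gazetteers: folded, punctuation
# squashed to single spaces, trimmed. Not lemmatized - proper names keep
# their surface form.
normalize_key <- function(x) {
  x <- fold_text(x)
  x <- gsub("[^a-z0-9]+", " ", x)
  trimws(gsub(" +", " ", x))
}

#' Tokenize text with character spans
#'
#' Splits text into word tokens (alphanumeric runs, allowing internal
#' apostrophes and hyphens) and redaction placeholders, reporting 0-based
#' half-open character spans into the input.
#'
#' @param text A single string.
#' @return Data frame with columns `surface`, `start`, `end`.
#' @export
tokenize <- function(text) {
  stopifnot(length(text) == 1L)
  if (is.na(text) || !nzchar(text)) {
    return(data.frame(surface = character(0), start = integer(0),
                      end = integer(0), stringsAsFactors = FALSE))
  }
  pat <- paste0(.placeholder_re, "|[[:alnum:]][[:alnum:]'’-]*")
  m <- gregexpr(pat, text, perl = TRUE)[[1]]
  if (m[1] == -1) {
    return(data.frame(surface = character(0), start = integer(0),
                      end = integer(0), stringsAsFactors = FALSE))
  }
  start <- as.integer(m) - 1L
  len <- attr(m, "match.length")
  data.frame(surface = substring(text, m, m + len - 1L),
             start = start, end = start + len,
             stringsAsFactors = FALSE)
}

# Lemma for each token surface (placeholders and pure punctuation yield "").
token_lemmas <- function(surfaces, lemmatizer = lemmatize_token) {
  vapply(surfaces, function(s) {
    if (grepl(paste0("^", .placeholder_re, "$"), s)) return("")
    s <- gsub("[^a-z0-9]+", "", fold_text(s))
    if (!nzchar(s)) return("")
    lemmatizer(s)
  }, character(1), USE.NAMES = FALSE)
}
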