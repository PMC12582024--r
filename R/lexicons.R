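# Curated dictionaries steering the hybrid de-identification:
# abbreviation expansions, medical allowlists (veto redaction) and the
# geographic denylist (force redaction).

#' Construct an abbreviation dictionary
#'
#' @param entries Named character vector or two-column data frame
#'   (abbreviation, expansion).
#' @param language ISO 639-1 language code of the abbreviations.
#' @return Object of class `ptx_abbrev`.
#' @export
abbreviation_dictionary <- function(entries, language = "en") {
  if (is.data.frame(entries)) {
    ab <- as.character(entries[[1]])
    ex <- as.character(entries[[2]])
  } else {
    ab <- names(entries)
    ex <- unname(as.character(entries))
  }
  if (anyDuplicated(ab)) {
    stop("duplicate abbreviation key(s): ",
         paste(unique(ab[duplicated(ab)]), collapse = ", "))
  }
  if (any(!nzchar(ex))) stop("abbreviation expansions must be non-empty")
  if (any(ab == ex)) stop("an abbreviation must differ from its expansion")
  structure(list(language = language,
                 entries = stats::setNames(ex, ab)),
            class = "ptx_abbrev")
}

#' Construct a gazetteer
#'
#' A gazetteer is a set of normalized phrases with a fixed polarity:
#' `allow` gazetteers (medical names, drugs, gene symbols) veto redaction;
#' the `deny` gazetteer (locations) forces it. Phrases are normalized to
#' lowercase accent-folded form at construction.
#'
#' @param phrases Character vector of phrases.
#' @param category One of `"medical_name"`, `"drug"`, `"gene"`, `"location"`.
#' @return Object of class `ptx_gazetteer` with fields `category`,
#'   `phrases`, `polarity` (`location` -> `deny`, others -> `allow`).
#' @export
gazetteer <- function(phrases, category = c("medical_name", "drug", "gene",
                                            "location")) {
  category <- match.arg(category)
  phrases <- unique(normalize_key(as.character(phrases)))
  phrases <- phrases[nzchar(phrases)]
  if (!length(phrases)) {
    warning("empty gazetteer (category ", category, ")")
  }
  structure(list(category = category, phrases = phrases,
                 polarity = if (category == "location") "deny" else "allow"),
            class = "ptx_gazetteer")
}

#' Test whether a gazetteer contains a phrase
#'
#' Matching is exact on the normalized (lowercase, accent-folded,
#' whitespace-squashed) form of the whole phrase; no substring matching.
#'
#' @param g A `ptx_gazetteer`.
#' @param phrase Character vector of query phrases.
#' @return Logical vector.
#' @export
gazetteer_contains <- function(g, phrase) {
  stopifnot(inherits(g, "ptx_gazetteer"))
  normalize_key(phrase) %in% g$phrases
}

#' Load a TSV lexicon
#'
#' Reads a UTF-8, header-carrying, tab-delimited lexicon. For
#' `kind = "abbrev"` the file must have columns `abbreviation` and
#' `expansion`; duplicate abbreviation keys are an error. For
#' `kind = "gazetteer"` the columns are `phrase` and `category`; duplicate
#' phrases are de-duplicated silently and one gazetteer is returned per
#' category present in the file.
#'
#' @param path Path to the TSV file.
#' @param kind `"abbrev"` or `"gazetteer"`.
#' @param language Language code recorded on an abbreviation dictionary.
#' @return A `ptx_abbrev`, or a named list of `ptx_gazetteer` (one per
#'   category).
#' @export
load_tsv_lexicon <- function(path, kind = c("abbrev", "gazetteer"),
                             language = "en") {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("cannot read lexicon file: ", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                          fileEncoding = "UTF-8", stringsAsFactors = FALSE,
                          colClasses = "character")
  need <- if (kind == "abbrev") c("abbreviation", "expansion")
          else c("phrase", "category")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop("lexicon ", path, " lacks required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  if (!nrow(df)) {
    warning("empty lexicon file: ", path)
    if (kind == "abbrev") {
      return(structure(list(language = language, entries = character(0)),
                       class = "ptx_abbrev"))
    }
    return(list())
  }
  if (kind == "abbrev") {
    return(abbreviation_dictionary(df[need], language = language))
  }
  cats <- unique(df$category)
  stats::setNames(
    lapply(cats, function(cc) gazetteer(df$phrase[df$category == cc],
                                        category = cc)),
    cats)
}
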