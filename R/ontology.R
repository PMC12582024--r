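# Phenotype ontology loading and the normalized synonym index used for
# sentence-level concept matching.

#' Load a phenotype ontology from an OBO flat file
#'
#' Parses the OBO 1.2 subset used by the Human Phenotype Ontology:
#' `[Term]` stanzas with `id`, `name`, `synonym`, `is_a`, `is_obsolete` and
#' `replaced_by` lines. Only terms in the HP namespace (ids of the form
#' `HP:` + 7 digits) are returned.
#'
#' @param path Path to an OBO file.
#' @param fmt Input format; only `"obo"` is supported.
#' @return An object of class `ptx_ontology`: a named list of terms, each a
#'   list with fields `id`, `name`, `synonyms`, `parents`, `obsolete`,
#'   `replaced_by`.
#' @export
load_ontology <- function(path, fmt = "obo") {
  fmt <- match.arg(fmt, "obo")
  if (!file.exists(path)) {
    stop("cannot read ontology file: ", path)
  }
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  terms <- list()
  cur <- NULL
  in_term <- FALSE
  flush <- function(cur) {
    if (is.null(cur)) return(invisible(NULL))
    if (is.null(cur$id) || is.null(cur$name)) {
      stop("malformed [Term] stanza near line ", cur$line,
           ": missing id or name")
    }
    if (grepl("^HP:\\d{7}$", cur$id)) {
      terms[[cur$id]] <<- list(
        id = cur$id, name = cur$name,
        synonyms = cur$synonyms %||% character(0),
        parents = cur$parents %||% character(0),
        obsolete = isTRUE(cur$obsolete),
        replaced_by = cur$replaced_by
      )
    }
    invisible(NULL)
  }
  for (i in seq_along(lines)) {
    ln <- trimws(lines[[i]])
    if (ln == "[Term]") {
      flush(cur)
      cur <- list(line = i, synonyms = character(0), parents = character(0))
      in_term <- TRUE
      next
    }
    if (grepl("^\\[", ln)) { # some other stanza type, e.g. [Typedef]
      flush(cur)
      cur <- NULL
      in_term <- FALSE
      next
    }
    if (!in_term || !nzchar(ln)) next
    if (!grepl("^[a-z_]+:", ln)) {
      stop("malformed OBO line ", i, ": ", ln)
    }
    key <- sub(":.*$", "", ln)
    val <- trimws(sub("^[a-z_]+:\\s*", "", ln))
    if (key == "id") cur$id <- val
    else if (key == "name") cur$name <- val
    else if (key == "synonym") {
      m <- regmatches(val, regexec("^\"(.*)\"", val))[[1]]
      if (length(m) < 2) stop("malformed synonym line ", i, ": ", ln)
      cur$synonyms <- c(cur$synonyms, m[2])
    } else if (key == "is_a") {
      cur$parents <- c(cur$parents, sub("\\s*!.*$", "", val))
    } else if (key == "is_obsolete") {
      cur$obsolete <- identical(val, "true")
    } else if (key == "replaced_by") {
      cur$replaced_by <- val
    }
    # other keys (def, xref, comment, ...) are ignored
  }
  flush(cur)
  if (!length(terms)) {
    stop("empty ontology: no [Term] stanzas in HP namespace found in ", path)
  }
  structure(terms, class = "ptx_ontology")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.ptx_ontology <- function(x, ...) {
  n_obs <- sum(vapply(x, function(t) t$obsolete, logical(1)))
  cat(sprintf("<ptx_ontology> %d terms (%d obsolete)\n", length(x), n_obs))
  invisible(x)
}

#' Build a normalized synonym index over non-obsolete ontology terms
#'
#' For every non-obsolete term, the name and each synonym are normalized with
#' [normalize_phrase()] into token sets; each non-empty set is inserted under
#' a canonical key. Two labels normalizing to the same key keep all term ids
#' under that key. Labels normalizing to the empty set are skipped with a
#' warning.
#'
#' @param terms A `ptx_ontology` or list of term records.
#' @param stopwords Tokens excluded from keys; defaults to
#'   [default_stopwords()].
#' @param lemmatizer Token lemmatizer passed through to [normalize_phrase()].
#' @return An object of class `ptx_index` with fields `entries` (named list,
#'   key -> data frame of `term_id`, `label`), `term_token_sets` (named list,
#'   term id -> list of `list(label=, tokens=)`), `labels` (term id -> name),
#'   `stopwords`.
#' @export
build_synonym_index <- function(terms, stopwords = default_stopwords(),
                                lemmatizer = lemmatize_token) {
  active <- Filter(function(t) !isTRUE(t$obsolete), terms)
  if (!length(active)) stop("no non-obsolete terms to index")
  entries <- list()
  tsets <- list()
  labels <- character(0)
  for (t in active) {
    labs <- c(t$name, t$synonyms)
    sets <- list()
    for (lab in labs) {
      tok <- normalize_phrase(lab, stopwords, lemmatizer)
      if (!length(tok)) {
        warning(sprintf("label '%s' of %s normalizes to the empty set; skipped",
                        lab, t$id))
        next
      }
      key <- paste(tok, collapse = " ")
      sets[[length(sets) + 1L]] <- list(label = lab, tokens = tok)
      row <- data.frame(term_id = t$id, label = lab, stringsAsFactors = FALSE)
      entries[[key]] <- if (is.null(entries[[key]])) row else
        rbind(entries[[key]], row)
    }
    if (length(sets)) {
      tsets[[t$id]] <- sets
      labels[[t$id]] <- t$name
    }
  }
  structure(list(entries = entries, term_token_sets = tsets,
                 labels = labels, stopwords = stopwords,
                 lemmatizer = lemmatizer),
            class = "ptx_index")
}

#' @export
print.ptx_index <- function(x, ...) {
  cat(sprintf("<ptx_index> %d terms, %d keys\n",
              length(x$term_token_sets), length(x$entries)))
  invisible(x)
}
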