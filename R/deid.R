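# Pipeline step (iii): rule-based PHI detection, hybrid allowlist veto /
# denylist force, span merging and redaction. All offsets are 0-based
# half-open character intervals into the text being scanned.

.category_priority <- c(PERSON = 1L, DATE_TIME = 2L, LOCATION = 3L,
                        ID = 4L, OTHER = 5L)

redaction_frame <- function(start = integer(0), end = integer(0),
                            category = character(0), source = character(0),
                            surface = character(0)) {
  data.frame(start = as.integer(start), end = as.integer(end),
             category = category, source = source, surface = surface,
             placeholder = if (length(category))
               paste0("<", category, ">") else character(0),
             stringsAsFactors = FALSE)
}

.match_frame <- function(text, m, category, source) {
  if (m[1] == -1) return(redaction_frame())
  st <- as.integer(m) - 1L
  len <- attr(m, "match.length")
  redaction_frame(st, st + len, rep(category, length(st)),
                  rep(source, length(st)),
                  substring(text, st + 1L, st + len))
}

.capture_frame <- function(text, m, group, category, source) {
  cs <- attr(m, "capture.start")
  cl <- attr(m, "capture.length")
  if (is.null(cs) || m[1] == -1) return(redaction_frame())
  st <- as.integer(cs[, group]) - 1L
  len <- as.integer(cl[, group])
  ok <- len > 0
  st <- st[ok]; len <- len[ok]
  redaction_frame(st, st + len, rep(category, length(st)),
                  rep(source, length(st)),
                  substring(text, st + 1L, st + len))
}

.months_en <- c("january", "february", "march", "april", "may", "june",
                "july", "august", "september", "october", "november",
                "december")
.months_fr <- c("janvier", "fevrier", "mars", "avril", "mai", "juin",
                "juillet", "aout", "septembre", "octobre", "novembre",
                "decembre")

#' Detect date and time expressions
#'
#' Matches numeric dates (`dd/mm/yyyy`, `dd.mm.yyyy`, `dd-mm-yyyy`,
#' `yyyy-mm-dd`), month-name dates in English plus a configurable
#' source-language month list (French by default), and standalone four-digit
#' years adjacent to the cues `born` or `in`. Matching is case- and
#' accent-insensitive.
#'
#' @param text A single string.
#' @param extra_months Additional (source-language) month names, matched on
#'   their accent-folded form.
#' @return Data frame of `DATE_TIME` redaction spans.
#' @export
detect_dates <- function(text, extra_months = .months_fr) {
  folded <- fold_text(text)
  months <- paste(c(.months_en, normalize_key(extra_months)), collapse = "|")
  out <- list()
  num <- paste0("(?<![0-9])(?<![0-9][/.-])(\\d{1,2}[/.-]\\d{1,2}[/.-]\\d{2,4}",
                "|\\d{4}-\\d{2}-\\d{2})(?!\\d)(?![/.-]\\d)")
  out[[1]] <- .match_frame(text, gregexpr(num, folded, perl = TRUE)[[1]],
                           "DATE_TIME", "detector")
  mn1 <- paste0("\\b\\d{1,2}(st|nd|rd|th)?\\s+(", months,
                ")(\\s+\\d{4})?\\b")
  out[[2]] <- .match_frame(text, gregexpr(mn1, folded, perl = TRUE)[[1]],
                           "DATE_TIME", "detector")
  mn2 <- paste0("\\b(", months, ")\\s+\\d{1,2}(st|nd|rd|th)?(,?\\s+\\d{4})?\\b")
  out[[3]] <- .match_frame(text, gregexpr(mn2, folded, perl = TRUE)[[1]],
                           "DATE_TIME", "detector")
  mn3 <- paste0("\\b(", months, ")\\s+\\d{4}\\b")
  out[[4]] <- .match_frame(text, gregexpr(mn3, folded, perl = TRUE)[[1]],
                           "DATE_TIME", "detector")
  yr <- "\\b(?:born|in)\\s+((?:19|20)\\d{2})\\b"
  out[[5]] <- .capture_frame(text, gregexpr(yr, folded, perl = TRUE)[[1]],
                             1L, "DATE_TIME", "detector")
  spans <- do.call(rbind, out)
  merge_spans(spans)
}

.default_titles <- c("Mr", "Mrs", "Ms", "Miss", "Dr", "Pr", "Prof",
                     "M", "Mme", "Mlle", "née", "nee", "born")

#' Detect person names
#'
#' Flags capitalized token sequences that follow a trigger title ("Mr",
#' "Mrs", "Dr", "née", "born", ...) and, when a name gazetteer is supplied,
#' every whole-word occurrence of a gazetteer name regardless of context.
#' The recognizer is pluggable: any function with this signature can stand
#' in for it in the pipeline configuration.
#'
#' @param text A single string.
#' @param triggers Title/trigger words preceding a name.
#' @param name_gazetteer Optional `ptx_gazetteer` of known names.
#' @return Data frame of `PERSON` redaction spans.
#' @export
detect_persons <- function(text, triggers = .default_titles,
                           name_gazetteer = NULL) {
  out <- list()
  trig <- paste(vapply(triggers, escape_regex, character(1)), collapse = "|")
  cap <- "\\p{Lu}[\\p{L}'’-]*"
  pat <- paste0("\\b(?:", trig, ")\\.?\\s+(", cap, "(?:\\s+", cap, ")*)")
  out[[1]] <- .capture_frame(text, gregexpr(pat, text, perl = TRUE)[[1]],
                             1L, "PERSON", "detector")
  if (!is.null(name_gazetteer)) {
    out[[2]] <- scan_gazetteer(text, name_gazetteer, "PERSON", "detector")
  }
  merge_spans(do.call(rbind, out))
}

# Whole-word occurrences of every gazetteer phrase, located on the folded
# text (folding is length-preserving, so offsets are valid in `text`).
scan_gazetteer <- function(text, g, category, source) {
  stopifnot(inherits(g, "ptx_gazetteer"))
  folded <- fold_text(text)
  out <- list()
  for (ph in g$phrases) {
    pat <- paste0("(?<![[:alnum:]])",
                  gsub(" ", "\\\\s+", escape_regex(ph)),
                  "(?![[:alnum:]])")
    m <- gregexpr(pat, folded, perl = TRUE)[[1]]
    f <- .match_frame(text, m, category, source)
    if (nrow(f)) out[[length(out) + 1L]] <- f
  }
  if (!length(out)) return(redaction_frame())
  do.call(rbind, out)
}

#' Detect locations from the geographic denylist
#'
#' Every whole-word occurrence of a denylist phrase yields a `LOCATION`
#' span with `source = "denylist"`; such spans are exempt from the
#' allowlist veto.
#'
#' @param text A single string.
#' @param denylist A `ptx_gazetteer` with polarity `deny`.
#' @return Data frame of `LOCATION` redaction spans.
#' @export
detect_locations <- function(text, denylist) {
  stopifnot(inherits(denylist, "ptx_gazetteer"))
  if (!identical(denylist$polarity, "deny")) {
    stop("detect_locations requires a deny-polarity gazetteer")
  }
  merge_spans(scan_gazetteer(text, denylist, "LOCATION", "denylist"))
}

#' Veto detector spans covered by an allowlist
#'
#' Removes any detector-sourced span whose surface, normalized, is an
#' allowlisted phrase, or which lies wholly inside an occurrence of an
#' allowlisted multi-word phrase in the text. Denylist-sourced spans are
#' never removed (privacy-first precedence). Removals are logged in
#' `attr(, "vetoed")` with the matching allowlist category.
#'
#' @param spans Data frame of redaction spans.
#' @param allowlists List of allow-polarity `ptx_gazetteer` objects.
#' @param text The text the spans index into.
#' @return Filtered span data frame.
#' @export
apply_allowlist <- function(spans, allowlists, text) {
  if (!nrow(spans) || !length(allowlists)) {
    attr(spans, "vetoed") <- redaction_frame()
    return(spans)
  }
  for (g in allowlists) {
    if (!identical(g$polarity, "allow")) {
      stop("apply_allowlist accepts allow-polarity gazetteers only")
    }
  }
  drop <- rep(FALSE, nrow(spans))
  why <- rep(NA_character_, nrow(spans))
  keys <- normalize_key(spans$surface)
  for (g in allowlists) {
    hit <- spans$source == "detector" & !drop & keys %in% g$phrases
    drop[hit] <- TRUE
    why[hit] <- g$category
    # containment in a multi-word allowlisted phrase occurrence
    multi <- g$phrases[grepl(" ", g$phrases)]
    if (length(multi)) {
      occ <- scan_gazetteer(text, gazetteer(multi, g$category),
                            "OTHER", "detector")
      for (i in which(spans$source == "detector" & !drop)) {
        inside <- occ$start <= spans$start[i] & spans$end[i] <= occ$end
        if (any(inside)) {
          drop[i] <- TRUE
          why[i] <- g$category
        }
      }
    }
  }
  out <- spans[!drop, , drop = FALSE]
  rownames(out) <- NULL
  vetoed <- spans[drop, , drop = FALSE]
  vetoed$allowlist_category <- why[drop]
  attr(out, "vetoed") <- vetoed
  out
}

#' Merge redaction spans
#'
#' Overlapping or adjacent (zero-gap) spans of the same category merge into
#' one. Overlapping spans of different categories keep the earlier-starting
#' span; ties at the same start are broken by category priority
#' `PERSON > DATE_TIME > LOCATION > ID > OTHER`. The result is sorted and
#' non-overlapping.
#'
#' @param spans Data frame of redaction spans (may be NULL or empty).
#' @param text Optional text to refresh `surface` strings of merged spans.
#' @return Sorted, non-overlapping span data frame.
#' @export
merge_spans <- function(spans, text = NULL) {
  if (is.null(spans) || !nrow(spans)) return(redaction_frame())
  pr <- .category_priority[spans$category]
  pr[is.na(pr)] <- 99L
  ord <- order(spans$start, pr, -(spans$end - spans$start))
  spans <- spans[ord, , drop = FALSE]
  out <- spans[1, , drop = FALSE]
  for (i in seq_len(nrow(spans))[-1]) {
    j <- nrow(out)
    cur <- spans[i, ]
    if (cur$start < out$end[j]) {
      if (identical(cur$category, out$category[j])) {
        out$end[j] <- max(out$end[j], cur$end)
        # a merged span keeps the stronger provenance: denylist spans are
        # exempt from the allowlist veto, so the union must stay exempt
        if (cur$source == "denylist") out$source[j] <- "denylist"
      }
      # different category: earlier-starting (or higher-priority) span wins
    } else if (cur$start == out$end[j] &&
               identical(cur$category, out$category[j])) {
      out$end[j] <- max(out$end[j], cur$end)
    } else {
      out <- rbind(out, cur)
    }
  }
  if (!is.null(text)) {
    out$surface <- substring(text, out$start + 1L, out$end)
  }
  out$placeholder <- paste0("<", out$category, ">")
  rownames(out) <- NULL
  out
}

#' Redact text
#'
#' Replaces each span's slice by its category placeholder, leaving all other
#' text byte-identical.
#'
#' @param text A single string.
#' @param spans Sorted, non-overlapping redaction spans within bounds.
#' @return List with `text` (de-identified string) and `report`: a data
#'   frame (`category`, `start`, `end`, `surface`, `placeholder`, `source`)
#'   with the original offsets, for audit.
#' @export
redact <- function(text, spans) {
  if (is.null(spans) || !nrow(spans)) {
    return(list(text = text,
                report = redaction_frame()[, c("category", "start", "end",
                                               "surface", "placeholder",
                                               "source")]))
  }
  if (is.unsorted(spans$start) ||
      any(spans$start[-1] < spans$end[-nrow(spans)])) {
    stop("redact() requires sorted, non-overlapping spans")
  }
  if (any(spans$start < 0) || any(spans$end > nchar(text)) ||
      any(spans$end <= spans$start)) {
    stop("redaction span out of bounds")
  }
  spans$surface <- substring(text, spans$start + 1L, spans$end)
  edits <- data.frame(start = spans$start, end = spans$end,
                      original = spans$surface,
                      replacement = spans$placeholder,
                      stringsAsFactors = FALSE)
  list(text = apply_edits(text, edits),
       report = spans[, c("category", "start", "end", "surface",
                          "placeholder", "source")])
}

#' De-identify text with the full hybrid rule set
#'
#' Runs the date, person and denylist location detectors, applies the
#' allowlist veto, merges spans and redacts.
#'
#' @param text A single string (normally the translated English text).
#' @param allowlists List of allow-polarity gazetteers (may be empty).
#' @param denylist Optional deny-polarity location gazetteer.
#' @param name_gazetteer Optional person-name gazetteer.
#' @param triggers Person-trigger titles.
#' @param extra_months Source-language month names for date detection.
#' @return List with `text`, `report` (as [redact()]) and `vetoed` (spans
#'   removed by the allowlist).
#' @export
deidentify <- function(text, allowlists = list(), denylist = NULL,
                       name_gazetteer = NULL, triggers = .default_titles,
                       extra_months = .months_fr) {
  spans <- rbind(
    detect_dates(text, extra_months),
    detect_persons(text, triggers, name_gazetteer),
    if (!is.null(denylist)) detect_locations(text, denylist) else
      redaction_frame()
  )
  spans <- apply_allowlist(merge_spans(spans, text), allowlists, text)
  vetoed <- attr(spans, "vetoed")
  res <- redact(text, merge_spans(spans, text))
  res$vetoed <- vetoed
  res
}
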