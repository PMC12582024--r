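# Orchestration of the four stages — expand, translate, de-identify,
# summarize — plus the output writers (de-identified text, CSV term list,
# PhenoTips-style JSON, TSV span report).

#' Pipeline configuration
#'
#' Bundles the loaded components every stage needs. Summarization runs on
#' the de-identified text; placeholders are never lemma-matched.
#'
#' @param index A `ptx_index` over the target ontology.
#' @param abbrev A `ptx_abbrev` dictionary (may hold zero entries).
#' @param engine A `ptx_engine`; defaults to the passthrough engine.
#' @param allowlists List of allow-polarity gazetteers.
#' @param denylist Optional deny-polarity location gazetteer.
#' @param name_gazetteer Optional person-name gazetteer.
#' @param cues A `ptx_cues` object.
#' @param language Source language the pipeline accepts.
#' @param emit Outputs to write: subset of `deid_text`, `csv`,
#'   `phenotips_json`, `span_report`.
#' @return Object of class `ptx_config`.
#' @export
pipeline_config <- function(index, abbrev = NULL,
                            engine = make_passthrough_engine(),
                            allowlists = list(), denylist = NULL,
                            name_gazetteer = NULL, cues = default_cues(),
                            language = engine$source_language,
                            emit = c("deid_text", "csv", "phenotips_json",
                                     "span_report")) {
  stopifnot(inherits(index, "ptx_index"), inherits(engine, "ptx_engine"))
  if (!identical(language, engine$source_language)) {
    stop("configured language is not supported by the engine")
  }
  emit <- match.arg(emit, several.ok = TRUE)
  structure(list(index = index, abbrev = abbrev, engine = engine,
                 allowlists = allowlists, denylist = denylist,
                 name_gazetteer = name_gazetteer, cues = cues,
                 language = language, emit = emit),
            class = "ptx_config")
}

#' Process one report through all four stages
#'
#' Stage order: (i) abbreviation expansion, (ii) translation,
#' (iii) de-identification, (iv) HPO summarization on the de-identified
#' text. Edit maps of the transforming stages are returned so annotation
#' spans (e.g. gold PHI spans) can be remapped across stages with
#' [remap_spans()].
#'
#' @param text Report text.
#' @param cfg A `ptx_config`.
#' @param doc_id Report identifier.
#' @return Object of class `ptx_result`: list with `doc_id`, `deid_text`,
#'   `hits` (a `ptx_hits` frame carrying a `report_id` column),
#'   `span_report`, `vetoed`, `expansion_edits`, `translation_edits`, and
#'   `log` (named per-stage counters).
#' @export
process_report <- function(text, cfg, doc_id = "doc") {
  stopifnot(inherits(cfg, "ptx_config"))
  doc <- document(text, doc_id = doc_id, language = cfg$language)
  # (i) expand
  if (!is.null(cfg$abbrev)) {
    exp <- expand_abbreviations(doc$text, cfg$abbrev)
    doc$text <- exp$text
    expansion_edits <- exp$edits
  } else {
    expansion_edits <- data.frame(start = integer(0), end = integer(0),
                                  original = character(0),
                                  replacement = character(0),
                                  stringsAsFactors = FALSE)
  }
  doc$stage <- "expanded"
  # (ii) translate
  doc <- translate_document(doc, cfg$engine)
  translation_edits <- attr(doc, "edits")
  # (iii) de-identify
  deid <- deidentify(doc$text, allowlists = cfg$allowlists,
                     denylist = cfg$denylist,
                     name_gazetteer = cfg$name_gazetteer)
  deid_doc <- document(deid$text, doc_id = doc_id, language = "en",
                       stage = "deidentified")
  # (iv) summarize the de-identified text
  hits <- summarize_document(deid_doc, cfg$index, cfg$cues)
  hits <- cbind(report_id = rep(doc_id, nrow(hits)), hits)
  structure(list(
    doc_id = doc_id, deid_text = deid$text, hits = hits,
    span_report = deid$report, vetoed = deid$vetoed,
    expansion_edits = expansion_edits,
    translation_edits = translation_edits,
    log = c(abbreviations_expanded = nrow(expansion_edits),
            spans_redacted = nrow(deid$report),
            spans_person = sum(deid$report$category == "PERSON"),
            spans_date = sum(deid$report$category == "DATE_TIME"),
            spans_location = sum(deid$report$category == "LOCATION"),
            spans_vetoed = nrow(deid$vetoed),
            hits_high = sum(hits$confidence == "high"),
            hits_low = sum(hits$confidence == "low"))),
    class = "ptx_result")
}

#' Run the pipeline over a set of reports and write outputs
#'
#' @param inputs Named character vector of report texts (names are report
#'   ids), or a character vector of file paths (ids from file names).
#' @param cfg A `ptx_config`.
#' @param output_dir Directory for the output bundle (created if needed).
#' @return Invisibly, a list of `ptx_result` (failed reports are `NULL`);
#'   attribute `status` is 0 if all reports succeeded, 1 on partial
#'   failure.
#' @export
run_pipeline <- function(inputs, cfg, output_dir) {
  stopifnot(inherits(cfg, "ptx_config"))
  if (!length(inputs)) stop("no input reports given")
  if (is.null(names(inputs))) {
    paths <- inputs
    inputs <- vapply(paths, function(p) {
      paste(readLines(p, encoding = "UTF-8", warn = FALSE), collapse = "\n")
    }, character(1))
    names(inputs) <- sub("\\.txt$", "", basename(paths))
  }
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  results <- vector("list", length(inputs))
  names(results) <- names(inputs)
  for (id in names(inputs)) {
    res <- tryCatch(process_report(inputs[[id]], cfg, doc_id = id),
                    error = function(e) {
      message(sprintf("report %s skipped: %s", id, conditionMessage(e)))
      NULL
    })
    results[[id]] <- res
    if (is.null(res)) next
    if ("deid_text" %in% cfg$emit) {
      writeLines(res$deid_text, file.path(output_dir,
                                          paste0(id, ".deid.txt")),
                 useBytes = TRUE)
    }
    if ("csv" %in% cfg$emit) {
      write_hits_csv(res$hits, file.path(output_dir, paste0(id, ".hpo.csv")))
    }
    if ("phenotips_json" %in% cfg$emit) {
      write_phenotips_json(res$hits,
                           file.path(output_dir,
                                     paste0(id, ".phenotips.json")))
    }
    if ("span_report" %in% cfg$emit) {
      utils::write.table(res$span_report,
                         file.path(output_dir, paste0(id, ".spans.tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE,
                         fileEncoding = "UTF-8")
    }
  }
  attr(results, "status") <- if (any(vapply(results, is.null, logical(1))))
    1L else 0L
  invisible(results)
}

csv_field <- function(x) {
  x[is.na(x)] <- ""
  needs <- grepl('[",\n]', x)
  x[needs] <- paste0('"', gsub('"', '""', x[needs]), '"')
  x
}

#' Write phenotype hits as CSV
#'
#' RFC 4180 CSV, UTF-8, LF line endings, with the fixed header
#' `report_id,hpo_id,hpo_label,confidence,reason,count,evidence_sentence,matched_text,quantitative`.
#' An empty hit list yields a header-only file. Missing quantitative values
#' become empty fields.
#'
#' @param hits A `ptx_hits` frame with a `report_id` column.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_hits_csv <- function(hits, path) {
  header <- paste("report_id", "hpo_id", "hpo_label", "confidence",
                  "reason", "count", "evidence_sentence", "matched_text",
                  "quantitative", sep = ",")
  lines <- header
  if (nrow(hits)) {
    rid <- if ("report_id" %in% names(hits)) hits$report_id
           else rep("doc", nrow(hits))
    rows <- paste(csv_field(rid), csv_field(hits$term_id),
                  csv_field(hits$label), csv_field(hits$confidence),
                  csv_field(hits$reason), hits$count,
                  hits$evidence_sentence, csv_field(hits$matched_text),
                  csv_field(hits$quantitative), sep = ",")
    lines <- c(lines, rows)
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

#' Read back a phenotype-hit CSV
#'
#' @param path Path written by [write_hits_csv()].
#' @return Data frame with the writer's columns.
#' @export
read_hits_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(quantitative = "character"),
                        fileEncoding = "UTF-8")
  df$quantitative[!nzchar(df$quantitative) |
                    is.na(df$quantitative)] <- NA_character_
  df
}

#' Write phenotype hits as PhenoTips-style JSON
#'
#' Emits `{"features": [...], "family_features": [...]}` where each element
#' is `{"id", "label", "type": "phenotype", "observed"}`. High-confidence
#' hits are observed `"yes"`; low-confidence negated hits observed `"no"`;
#' low-confidence family hits go under `family_features` (observed
#' `"yes"` for the relative). Arrays are ordered by first occurrence
#' offset. The file ends with a newline.
#'
#' @param hits A `ptx_hits` frame.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_phenotips_json <- function(hits, path) {
  feature <- function(h, observed) {
    list(id = h$term_id, label = h$label, type = "phenotype",
         observed = observed)
  }
  hits <- hits[order(hits$first_offset), , drop = FALSE]
  features <- list()
  family <- list()
  for (i in seq_len(nrow(hits))) {
    h <- hits[i, ]
    if (h$reason == "family") {
      family[[length(family) + 1L]] <- feature(h, "yes")
    } else {
      features[[length(features) + 1L]] <-
        feature(h, if (h$confidence == "high") "yes" else "no")
    }
  }
  json <- jsonlite::toJSON(list(features = features,
                                family_features = family),
                           auto_unbox = TRUE, pretty = TRUE)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(json, con, sep = "\n", useBytes = TRUE)
  invisible(path)
}
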