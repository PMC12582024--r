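# Evaluation machinery: TP/FP/FN accounting for de-identification and HPO
# summarization, severity filtering, and recall/precision/F1 with
# half-up rounding to the printed precision.

#' Round half-up
#'
#' Rounds to `digits` decimal places with ties going away from zero for
#' positive values (`0.5 -> 1`), matching how the benchmark percentages are
#' printed (banker's rounding of base `round()` would disagree on ties).
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  floor(x * p + 0.5 + sqrt(.Machine$double.eps)) / p
}

#' Construct a TP/FP/FN count record
#'
#' @param tp,fp,fn Non-negative integer counts.
#' @return Object of class `ptx_counts`.
#' @export
eval_counts <- function(tp = 0, fp = 0, fn = 0) {
  stopifnot(tp >= 0, fp >= 0, fn >= 0)
  structure(list(tp = as.integer(tp), fp = as.integer(fp),
                 fn = as.integer(fn)),
            class = "ptx_counts")
}

#' Recall, precision and F1 from confusion counts
#'
#' Recall = TP/(TP+FN) and precision = TP/(TP+FP), each reported as an
#' integer percentage rounded half-up; F1 is computed from the *unrounded*
#' fractions and rounded to two decimals. When either denominator is zero
#' the result is marked undefined and the values are `NA`.
#'
#' @param c A `ptx_counts` record.
#' @return Object of class `ptx_metrics` with fields `recall_pct`,
#'   `precision_pct`, `f1`, `defined`.
#' @export
compute_metrics <- function(c) {
  stopifnot(inherits(c, "ptx_counts"))
  if ((c$tp + c$fn) == 0 || (c$tp + c$fp) == 0) {
    return(structure(list(recall_pct = NA_real_, precision_pct = NA_real_,
                          f1 = NA_real_, defined = FALSE),
                     class = "ptx_metrics"))
  }
  r <- c$tp / (c$tp + c$fn)
  p <- c$tp / (c$tp + c$fp)
  f1 <- if ((p + r) > 0) 2 * p * r / (p + r) else 0
  structure(list(recall_pct = round_half_up(100 * r),
                 precision_pct = round_half_up(100 * p),
                 f1 = round_half_up(f1, 2), defined = TRUE),
            class = "ptx_metrics")
}

#' @export
print.ptx_metrics <- function(x, ...) {
  if (!x$defined) {
    cat("<ptx_metrics> undefined (zero denominator)\n")
  } else {
    cat(sprintf("<ptx_metrics> recall %g%%, precision %g%%, F1 %.2f\n",
                x$recall_pct, x$precision_pct, x$f1))
  }
  invisible(x)
}

#' Construct an error record
#'
#' @param kind One of `deid_fn`, `deid_fp`, `hpo_fp`, `hpo_fn`.
#' @param severity One of `major`, `moderate`, `minor`.
#' @param note Free-text explanation.
#' @return One-row data frame.
#' @export
error_record <- function(kind = c("deid_fn", "deid_fp", "hpo_fp", "hpo_fn"),
                         severity = c("major", "moderate", "minor"),
                         note = "") {
  data.frame(kind = match.arg(kind), severity = match.arg(severity),
             note = note, stringsAsFactors = FALSE)
}

#' Filter false positives by severity
#'
#' Recomputes the FP count keeping only false positives of the given
#' severities; TP and FN are untouched. There must be exactly one
#' `deid_fp` error record per counted FP.
#'
#' @param errors Data frame of error records (columns `kind`, `severity`).
#' @param c A `ptx_counts` record.
#' @param keep Character vector of severities to keep.
#' @return A new `ptx_counts` record.
#' @export
filter_counts_by_severity <- function(errors, c, keep) {
  stopifnot(inherits(c, "ptx_counts"))
  fp_rec <- errors[errors$kind == "deid_fp", , drop = FALSE]
  if (nrow(fp_rec) != c$fp) {
    stop(sprintf("inconsistent records: %d deid_fp records for fp=%d",
                 nrow(fp_rec), c$fp))
  }
  excluded <- sum(!(fp_rec$severity %in% keep))
  eval_counts(tp = c$tp, fp = c$fp - excluded, fn = c$fn)
}

#' Mean count per report
#'
#' @param total Non-negative total count.
#' @param n_reports Positive number of reports.
#' @return `total / n_reports` rounded half-up to one decimal.
#' @export
mean_per_report <- function(total, n_reports) {
  stopifnot(total >= 0)
  if (n_reports <= 0) stop("n_reports must be positive")
  round_half_up(total / n_reports, 1)
}

#' Compare predicted phenotype hits against a gold term set
#'
#' Comparison is on exact term ids over the distinct predicted ids
#' (optionally restricted to high-confidence hits).
#'
#' @param predicted A `ptx_hits` data frame (or any data frame with
#'   `term_id` and `confidence` columns).
#' @param gold Character vector of gold term ids.
#' @param mode `"all"` or `"high_only"`.
#' @return A `ptx_counts` record.
#' @export
compare_hpo_sets <- function(predicted, gold, mode = c("all", "high_only")) {
  mode <- match.arg(mode)
  gold <- unique(gold)
  ids <- predicted$term_id
  if (mode == "high_only") ids <- ids[predicted$confidence == "high"]
  ids <- unique(ids)
  eval_counts(tp = length(intersect(ids, gold)),
              fp = length(setdiff(ids, gold)),
              fn = length(setdiff(gold, ids)))
}

#' Compare predicted PHI spans against gold spans
#'
#' A gold span counts as detected (TP) if any predicted span overlaps it by
#' at least one character; category labels are not compared (detection
#' events are what matters for leak counting; partial redactions are graded
#' separately by severity). Gold spans with no overlapping prediction are
#' FN; predicted spans overlapping no gold span are FP.
#'
#' @param predicted Data frame with `start`, `end` columns (0-based,
#'   half-open), non-overlapping.
#' @param gold Data frame with `start`, `end` columns, non-overlapping.
#' @return A `ptx_counts` record.
#' @export
compare_phi_spans <- function(predicted, gold) {
  check_disjoint <- function(df, what) {
    if (nrow(df) < 2) return(invisible(NULL))
    df <- df[order(df$start), ]
    if (any(df$start[-1] < df$end[-nrow(df)])) {
      stop("overlapping spans within ", what, " list")
    }
  }
  check_disjoint(predicted, "predicted")
  check_disjoint(gold, "gold")
  overlaps <- function(s1, e1, s2, e2) s1 < e2 & s2 < e1
  gold_hit <- vapply(seq_len(nrow(gold)), function(i) {
    any(overlaps(gold$start[i], gold$end[i], predicted$start, predicted$end))
  }, logical(1))
  pred_hit <- vapply(seq_len(nrow(predicted)), function(i) {
    any(overlaps(predicted$start[i], predicted$end[i], gold$start, gold$end))
  }, logical(1))
  eval_counts(tp = sum(gold_hit), fn = sum(!gold_hit), fp = sum(!pred_hit))
}

#' Read a gold-annotation TSV
#'
#' Schema: `doc_id`, `kind` (`phi` or `hpo`), `start`, `end`,
#' `category_or_term_id` (tab-delimited, header row).
#'
#' @param path Path to the TSV.
#' @return Data frame.
#' @export
read_gold_tsv <- function(path) {
  df <- utils::read.delim(path, sep = "\t", quote = "", header = TRUE,
                          fileEncoding = "UTF-8", stringsAsFactors = FALSE)
  need <- c("doc_id", "kind", "start", "end", "category_or_term_id")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop("gold TSV lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  df
}
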