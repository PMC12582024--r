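span_text <- function(text, spans) {
  substring(text, spans$start + 1, spans$end)
}

test_that("date detection covers numeric, month-name and cued-year forms", {
  t1 <- "The patient was seen on 12/03/2023."
  d1 <- detect_dates(t1)
  expect_identical(span_text(t1, d1), "12/03/2023")
  t2 <- "Assessment on 12 March 2023 went well."
  expect_identical(span_text(t2, detect_dates(t2)), "12 March 2023")
  t3 <- "Examen le 14 juillet 2021."
  expect_identical(span_text(t3, detect_dates(t3)), "14 juillet 2021")
  t4 <- "Review on 2020-05-07."
  expect_identical(span_text(t4, detect_dates(t4)), "2020-05-07")
  t5 <- "She was born in 2019 at term."
  expect_identical(span_text(t5, detect_dates(t5)), "2019")
  # a bare number without a date cue is not a date
  expect_identical(nrow(detect_dates("trisomy 2023 panel")), 0L)
  expect_identical(nrow(detect_dates("karyotype 46,XX")), 0L)
})

test_that("person detection uses triggers and the name gazetteer", {
  t1 <- "Mr Dupont was seen today."
  p1 <- detect_persons(t1)
  expect_identical(p1$category, "PERSON")
  expect_identical(span_text(t1, p1), "Dupont")
  t2 <- "The mother, née Martin, is healthy."
  expect_identical(span_text(t2, detect_persons(t2)), "Martin")
  # no trigger, no gazetteer, lowercase: nothing to flag
  expect_identical(nrow(detect_persons("noonan syndrome suspected")), 0L)
  # gazetteer names are flagged wherever they occur
  g <- gazetteer("Lefevre", "medical_name")
  t3 <- "Lefevre came alone."
  expect_identical(span_text(t3, detect_persons(t3, name_gazetteer = g)),
                   "Lefevre")
})

test_that("denylist locations force redaction wherever they occur", {
  deny <- gazetteer(c("montpellier", "nîmes"), "location")
  t1 <- "The family lives in Nîmes."
  l1 <- detect_locations(t1, deny)
  expect_identical(span_text(t1, l1), "Nîmes")
  expect_identical(l1$source, "denylist")
  expect_identical(nrow(detect_locations("No places here.", deny)), 0L)
  t2 <- "From Montpellier to Montpellier."
  expect_identical(nrow(detect_locations(t2, deny)), 2L)
  allow <- gazetteer("x", "drug")
  expect_error(detect_locations(t1, allow), "deny")
})

test_that("the allowlist vetoes detector spans but never denylist spans", {
  allow <- list(gazetteer(c("Noonan", "Iso Kikuchi"), "medical_name"))
  t1 <- "Seen by Dr Noonan for follow-up."
  s1 <- detect_persons(t1)
  expect_identical(span_text(t1, s1), "Noonan")
  kept <- apply_allowlist(s1, allow, t1)
  expect_identical(nrow(kept), 0L)
  expect_identical(attr(kept, "vetoed")$allowlist_category, "medical_name")
  # a span lying inside an allowlisted multi-word phrase occurrence
  t2 <- "Features of Iso Kikuchi syndrome as described by Dr Iso."
  s2 <- redaction_spans_for_test(t2, "Iso", "PERSON", "detector")
  kept2 <- apply_allowlist(s2, allow, t2)
  expect_identical(nrow(kept2), 0L)
  # denylist spans survive even when their surface is allowlisted
  deny <- gazetteer("noonan", "location")
  s3 <- detect_locations("They visited Noonan yesterday.", deny)
  kept3 <- apply_allowlist(s3, allow, "They visited Noonan yesterday.")
  expect_identical(nrow(kept3), 1L)
})

test_that("span merging is category-aware and priority-ordered", {
  expect_identical(nrow(merge_spans(NULL)), 0L)
  a <- data.frame(start = c(0L, 5L), end = c(8L, 12L),
                  category = "DATE_TIME", source = "detector",
                  surface = "x", placeholder = "<DATE_TIME>")
  m <- merge_spans(a)
  expect_identical(nrow(m), 1L)
  expect_identical(c(m$start, m$end), c(0L, 12L))
  # overlap across categories: earlier start wins; tie -> PERSON outranks
  b <- data.frame(start = c(5L, 5L), end = c(10L, 12L),
                  category = c("PERSON", "LOCATION"), source = "detector",
                  surface = "x", placeholder = c("<PERSON>", "<LOCATION>"))
  m2 <- merge_spans(b)
  expect_identical(m2$category, "PERSON")
  # adjacent same-category spans merge (gap = 0)
  c3 <- data.frame(start = c(0L, 4L), end = c(4L, 9L),
                   category = "PERSON", source = "detector",
                   surface = "x", placeholder = "<PERSON>")
  expect_identical(nrow(merge_spans(c3)), 1L)
})

test_that("redaction substitutes placeholders and preserves the rest", {
  t1 <- "Mr Dupont, 12/03/2023"
  spans <- merge_spans(rbind(detect_persons(t1), detect_dates(t1)))
  r <- redact(t1, spans)
  expect_identical(r$text, "Mr <PERSON>, <DATE_TIME>")
  expect_identical(r$report$surface, c("Dupont", "12/03/2023"))
  # no spans -> identity
  expect_identical(redact("plain text", merge_spans(NULL))$text,
                   "plain text")
  # overlapping input is a contract violation
  bad <- data.frame(start = c(0L, 3L), end = c(5L, 8L),
                    category = "PERSON", source = "detector",
                    surface = "x", placeholder = "<PERSON>")
  expect_error(redact("abcdefghij", bad), "non-overlapping")
})

test_that("placeholder count equals span count across synthetic reports", {
  setup <- synth_setup(seed = 5L)
  corp <- generate_corpus(generator_config(seed = 5L, n_reports = 4L),
                          setup$ontology, setup$lexicons)
  for (rep in corp$reports) {
    res <- deidentify(rep$text, allowlists = setup$lexicons$allowlists,
                      denylist = setup$lexicons$denylist,
                      name_gazetteer = setup$lexicons$names)
    n_ph <- sum(lengths(regmatches(
      res$text, gregexpr("<(PERSON|DATE_TIME|LOCATION|ID|OTHER)>",
                         res$text))))
    expect_identical(n_ph, nrow(res$report))
    # text outside spans is preserved byte-identically
    keep <- res$report
    orig_parts <- character(0)
    pos <- 0L
    for (i in seq_len(nrow(keep))) {
      orig_parts <- c(orig_parts, substring(rep$text, pos + 1, keep$start[i]))
      pos <- keep$end[i]
    }
    orig_parts <- c(orig_parts, substring(rep$text, pos + 1))
    recon <- paste0(orig_parts,
                    c(keep$placeholder, ""), collapse = "")
    expect_identical(res$text, recon)
  }
})

test_that("redaction is order-independent", {
  t1 <- "Mr Dupont of Nîmes seen 12/03/2023 and 13/03/2023."
  deny <- gazetteer("nîmes", "location")
  spans <- rbind(detect_persons(t1), detect_dates(t1),
                 detect_locations(t1, deny))
  shuffles <- list(spans, spans[rev(seq_len(nrow(spans))), ],
                   spans[sample(nrow(spans)), ])
  texts <- vapply(shuffles, function(s) redact(t1, merge_spans(s))$text,
                  character(1))
  expect_identical(texts[1], texts[2])
  expect_identical(texts[1], texts[3])
})
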