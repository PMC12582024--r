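annotated <- function(text, stage = "translated") {
  annotate_document(document(text, stage = stage))
}

test_that("sentence matching finds terms by token-subset over lemmas", {
  idx <- tiny_index()
  doc <- annotated("He has seizures and microcephaly today.")
  h <- match_sentence(doc$sentences[[1]], idx, doc$text)
  expect_setequal(h$term_id, c("HP:0001250", "HP:0000252"))
  expect_true("seizures" %in% h$matched_text)
  # synonym tokens match too, across intervening words
  doc2 <- annotated("A small and rather round head was noted.")
  h2 <- match_sentence(doc2$sentences[[1]], idx, doc2$text)
  expect_identical(h2$term_id, "HP:0000252")
  expect_identical(h2$matched_text, "small and rather round head")
  # no indexed lemma -> no hits
  doc3 <- annotated("Follow-up went well.")
  expect_identical(nrow(match_sentence(doc3$sentences[[1]], idx, doc3$text)),
                   0L)
})

test_that("negation and family cues are detected at sentence scope", {
  cues <- default_cues()
  s <- function(t) annotated(t)$sentences[[1]]
  expect_true(detect_negation(s("No seizures were observed."), cues))
  expect_false(detect_negation(s("Seizures since age 2."), cues))
  expect_true(detect_negation(s("Absence of speech."), cues))
  expect_true(detect_negation(s("She denies headaches."), cues))
  expect_true(detect_family(s("His mother has microcephaly."), cues))
  expect_true(detect_family(s("Family history of epilepsy."), cues))
  expect_false(detect_family(s("The patient has microcephaly."), cues))
})

test_that("quantitative evidence picks the nearest measurement", {
  doc <- annotated("Microcephaly at -2.5 SD was found.")
  sent <- doc$sentences[[1]]
  expect_identical(extract_quantitative(sent, doc$text, 0L, 12L), "-2.5 SD")
  doc2 <- annotated("He has seizures.")
  expect_identical(extract_quantitative(doc2$sentences[[1]], doc2$text,
                                        7L, 15L), NA_character_)
  # two measurements: smallest token distance to the match wins
  t3 <- "Height 97th percentile noted today with microcephaly at -3 SD."
  doc3 <- annotated(t3)
  at <- regexpr("microcephaly", t3) - 1L
  got <- extract_quantitative(doc3$sentences[[1]], doc3$text,
                              as.integer(at), as.integer(at) + 12L)
  # oracle: exhaustive token-distance computation over both measurements
  expect_identical(got, "-3 SD")
})

test_that("document summaries flag confidence by cue context", {
  idx <- tiny_index()
  txt <- paste("The patient has seizures.",
               "His mother has microcephaly.",
               "No cleft palate was seen.")
  hits <- summarize_document(document(txt, stage = "translated"), idx)
  expect_identical(nrow(hits), 3L)
  expect_identical(hits$confidence, c("high", "low", "low"))
  expect_identical(hits$reason, c("affirmed", "family", "negated"))
  expect_identical(hits$evidence_sentence, 1:3)
  # empty document
  expect_identical(nrow(summarize_document(document("", stage = "translated"),
                                           idx)), 0L)
})

test_that("any affirmed occurrence promotes a term to high confidence", {
  idx <- tiny_index()
  txt <- paste("Seizures began at age one.",
               "Review was unremarkable.",
               "Her brother is healthy.",
               "No further seizures were seen.")
  hits <- summarize_document(document(txt, stage = "translated"), idx)
  expect_identical(nrow(hits), 1L)
  expect_identical(hits$confidence, "high")
  expect_identical(hits$reason, "affirmed")
  expect_identical(hits$count, 2L)
})

test_that("hits partition into affirmed/negated/family and stay deterministic", {
  setup <- synth_setup(seed = 9L)
  corp <- generate_corpus(generator_config(seed = 9L, n_reports = 5L),
                          setup$ontology, setup$lexicons)
  for (rep in corp$reports) {
    doc <- document(rep$text, stage = "translated")
    h1 <- summarize_document(doc, setup$index)
    h2 <- summarize_document(doc, setup$index)
    expect_identical(h1, h2)
    n_ha <- sum(h1$confidence == "high" & h1$reason == "affirmed")
    n_ln <- sum(h1$confidence == "low" & h1$reason == "negated")
    n_lf <- sum(h1$confidence == "low" & h1$reason == "family")
    expect_identical(n_ha + n_ln + n_lf, nrow(h1))
    # reason = affirmed <=> confidence = high
    expect_identical(h1$reason == "affirmed", h1$confidence == "high")
    # term ids unique per document
    expect_false(anyDuplicated(h1$term_id) > 0)
    expect_true(all(h1$count >= 1L))
    expect_false(is.unsorted(h1$first_offset))
  }
})

test_that("adding a sentence never removes a hit or downgrades confidence", {
  idx <- tiny_index()
  base <- "The patient has seizures. His mother has microcephaly."
  additions <- c("No cleft palate was seen.",
                 "Small head noted at review.",
                 "Seizures persisted.")
  h0 <- summarize_document(document(base, stage = "translated"), idx)
  for (extra in additions) {
    h1 <- summarize_document(document(paste(base, extra),
                                      stage = "translated"), idx)
    for (i in seq_len(nrow(h0))) {
      j <- match(h0$term_id[i], h1$term_id)
      expect_false(is.na(j))
      if (h0$confidence[i] == "high") {
        expect_identical(h1$confidence[j], "high")
      }
    }
  }
})

test_that("matching agrees with the brute-force subset oracle", {
  setup <- synth_setup(seed = 13L)
  corp <- generate_corpus(generator_config(seed = 13L, n_reports = 5L),
                          setup$ontology, setup$lexicons)
  n_checked <- 0L
  for (rep in corp$reports) {
    doc <- annotate_document(document(rep$text, stage = "translated"))
    for (sent in doc$sentences) {
      got <- sort(unique(match_sentence(sent, setup$index, doc$text)$term_id))
      want <- oracle_match_sentence(
        substring(doc$text, sent$span[["start"]] + 1, sent$span[["end"]]),
        setup$ontology)
      expect_identical(got, want)
      n_checked <- n_checked + 1L
    }
  }
  expect_gt(n_checked, 100L)
})
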