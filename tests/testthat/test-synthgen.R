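test_that("fixture ontologies are deterministic, parseable and well-formed", {
  o1 <- make_fixture_ontology(seed = 1, n_terms = 20)
  o2 <- make_fixture_ontology(seed = 1, n_terms = 20)
  expect_identical(o1, o2)
  expect_false(identical(o1, make_fixture_ontology(seed = 2, n_terms = 20)))
  p <- tempfile(fileext = ".obo")
  writeLines(o1, p, sep = "")
  ont <- load_ontology(p)
  expect_length(ont, 20L)
  obs <- Filter(function(t) t$obsolete, ont)
  expect_length(obs, 1L)
  # the obsolete term never enters the index
  idx <- build_synonym_index(ont)
  expect_false(obs[[1]]$id %in% names(idx$term_token_sets))
  # >= 30% of terms carry synonyms
  active <- Filter(function(t) !t$obsolete, ont)
  with_syn <- sum(vapply(active, function(t) length(t$synonyms) > 0,
                         logical(1)))
  expect_gte(with_syn / length(active), 0.3)
  # is_a links point inside the ontology
  for (t in ont) expect_true(all(t$parents %in% names(ont)))
  expect_error(make_fixture_ontology(1, 4), "at least 5")
})

test_that("generated corpora honour configured rates and are reproducible", {
  setup <- synth_setup(seed = 21L)
  cfg <- generator_config(seed = 21L, n_reports = 6L)
  c1 <- generate_corpus(cfg, setup$ontology, setup$lexicons)
  c2 <- generate_corpus(cfg, setup$ontology, setup$lexicons)
  expect_identical(c1, c2)
  for (rep in c1$reports) {
    expect_identical(nrow(rep$gold$phi_spans), 15L)
    expect_identical(nrow(rep$gold$hpo_terms), 7L)
    expect_identical(nrow(rep$gold$abbreviation_sites), 3L)
  }
  # fraction_negated = 1 -> every gold record expects (low, negated)
  all_neg <- generate_corpus(
    generator_config(seed = 3L, n_reports = 2L, frac_negated = 1,
                     frac_family = 0, abbrev_per_report = 0L),
    setup$ontology, setup$lexicons)
  for (rep in all_neg$reports) {
    expect_true(all(rep$gold$hpo_terms$confidence == "low"))
    expect_true(all(rep$gold$hpo_terms$reason == "negated"))
  }
  # PHI rate 0 -> no gold PHI spans
  no_phi <- generate_corpus(
    generator_config(seed = 3L, n_reports = 2L, phi_per_report = 0L),
    setup$ontology, setup$lexicons)
  for (rep in no_phi$reports) {
    expect_identical(nrow(rep$gold$phi_spans), 0L)
  }
})

test_that("gold spans slice to exactly the planted surface strings", {
  setup <- synth_setup(seed = 8L)
  corp <- generate_corpus(generator_config(seed = 8L, n_reports = 5L),
                          setup$ontology, setup$lexicons)
  for (rep in corp$reports) {
    g <- rep$gold$phi_spans
    expect_identical(substring(rep$text, g$start + 1, g$end), g$surface)
    a <- rep$gold$abbreviation_sites
    keys <- substring(rep$text, a$start + 1, a$end)
    expect_true(all(keys %in% names(setup$lexicons$abbrev$entries)))
  }
})

test_that("unsatisfiable generator configurations are rejected", {
  expect_error(generator_config(frac_negated = 1.2), "fractions")
  expect_error(generator_config(frac_negated = 0.8, frac_family = 0.6),
               "exceed")
  expect_error(generator_config(n_reports = 0), "positive")
  # ontology too small for the requested phenotype load
  small <- build_synonym_index(tiny_ontology())
  ont <- tiny_ontology()
  expect_error(
    generate_corpus(generator_config(seed = 1, n_reports = 1),
                    ont, synth_lexicons()),
    "plantable")
})

test_that("written corpora round-trip through the gold TSV reader", {
  setup <- synth_setup(seed = 4L)
  corp <- generate_corpus(generator_config(seed = 4L, n_reports = 2L),
                          setup$ontology, setup$lexicons)
  dir <- write_corpus(corp, tempfile("synthdir"),
                      obo_text = make_fixture_ontology(4L, 42L))
  expect_true(file.exists(file.path(dir, "report_001.txt")))
  expect_true(file.exists(file.path(dir, "fixture.obo")))
  g <- read_gold_tsv(file.path(dir, "report_001.gold.tsv"))
  gp <- g[g$kind == "phi", ]
  expect_identical(nrow(gp), nrow(corp$reports[[1]]$gold$phi_spans))
  txt <- paste(readLines(file.path(dir, "report_001.txt")), collapse = "\n")
  expect_identical(substring(txt, gp$start + 1, gp$end),
                   corp$reports[[1]]$gold$phi_spans$surface)
})
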