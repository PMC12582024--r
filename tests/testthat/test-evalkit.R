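test_that("metrics reproduce printed percentages under half-up rounding", {
  m <- compute_metrics(eval_counts(tp = 443, fp = 133, fn = 6))
  expect_identical(m$recall_pct, 99)
  expect_identical(m$precision_pct, 77)
  m2 <- compute_metrics(eval_counts(tp = 125, fp = 130, fn = 40))
  expect_identical(m2$precision_pct, 49)
  # perfect counts
  m3 <- compute_metrics(eval_counts(tp = 7, fp = 0, fn = 0))
  expect_identical(m3$recall_pct, 100)
  expect_identical(m3$precision_pct, 100)
  expect_identical(m3$f1, 1)
  # degenerate counts are undefined, not an error
  m4 <- compute_metrics(eval_counts(0, 0, 0))
  expect_false(m4$defined)
  expect_true(is.na(m4$recall_pct))
})

test_that("half-up rounding breaks ties away from zero", {
  expect_identical(round_half_up(0.5), 1)
  expect_identical(round_half_up(1.25, 1), 1.3)
  expect_identical(round_half_up(6.64, 1), 6.6)
  expect_identical(round_half_up(76.909), 77)
  # base round() would give 0 here (banker's rounding)
  expect_identical(round_half_up(0.5), 1)
})

test_that("severity filtering reduces only the false-positive count", {
  errs <- rbind(
    do.call(rbind, replicate(9, error_record("deid_fp", "major"),
                             simplify = FALSE)),
    do.call(rbind, replicate(55, error_record("deid_fp", "moderate"),
                             simplify = FALSE)),
    do.call(rbind, replicate(69, error_record("deid_fp", "minor"),
                             simplify = FALSE)))
  c0 <- eval_counts(tp = 443, fp = 133, fn = 6)
  c1 <- filter_counts_by_severity(errs, c0, keep = c("major", "moderate"))
  expect_identical(c1$fp, 64L)
  expect_identical(c1$tp, 443L)
  expect_identical(c1$fn, 6L)
  expect_identical(compute_metrics(c1)$precision_pct, 87)
  # keep-all is the identity; empty keep zeroes fp when all minor
  expect_identical(filter_counts_by_severity(errs, c0,
                                             c("major", "moderate",
                                               "minor"))$fp, 133L)
  all_minor <- do.call(rbind, replicate(3, error_record("deid_fp", "minor"),
                                        simplify = FALSE))
  expect_identical(filter_counts_by_severity(all_minor, eval_counts(fp = 3),
                                             character(0))$fp, 0L)
  # record/count mismatch is a consistency error
  expect_error(filter_counts_by_severity(all_minor, eval_counts(fp = 5),
                                         "major"), "inconsistent")
})

test_that("per-report means round half-up to one decimal", {
  expect_identical(mean_per_report(332, 50), 6.6)
  expect_identical(mean_per_report(0, 50), 0)
  expect_identical(mean_per_report(7, 2), 3.5)
  expect_error(mean_per_report(10, 0), "positive")
})

test_that("HPO set comparison counts distinct exact term ids", {
  pred <- data.frame(term_id = c("HP:0000001", "HP:0000002"),
                     confidence = c("high", "low"))
  gold <- c("HP:0000001", "HP:0000002")
  c_high <- compare_hpo_sets(pred, gold, "high_only")
  expect_identical(c(c_high$tp, c_high$fp, c_high$fn), c(1L, 0L, 1L))
  c_all <- compare_hpo_sets(pred, gold, "all")
  expect_identical(c(c_all$tp, c_all$fp, c_all$fn), c(2L, 0L, 0L))
  c_miss <- compare_hpo_sets(data.frame(term_id = "HP:0000003",
                                        confidence = "high"),
                             "HP:0000001", "all")
  expect_identical(c(c_miss$tp, c_miss$fp, c_miss$fn), c(0L, 1L, 1L))
})

test_that("HPO comparison conserves totals for arbitrary predictions", {
  set.seed(42)
  universe <- sprintf("HP:%07d", 1:30)
  for (i in 1:20) {
    pred <- data.frame(term_id = sample(universe, sample(1:12, 1)))
    pred$confidence <- sample(c("high", "low"), nrow(pred), replace = TRUE)
    gold <- sample(universe, sample(1:12, 1))
    for (mode in c("all", "high_only")) {
      cc <- compare_hpo_sets(pred, gold, mode)
      expect_identical(cc$tp + cc$fn, length(unique(gold)))
      n_pred <- if (mode == "all") length(unique(pred$term_id)) else
        length(unique(pred$term_id[pred$confidence == "high"]))
      expect_identical(cc$tp + cc$fp, n_pred)
    }
  }
})

test_that("PHI span comparison credits any one-character overlap", {
  gold <- data.frame(start = 10L, end = 20L)
  exact <- data.frame(start = 10L, end = 20L)
  expect_identical(compare_phi_spans(exact, gold)$tp, 1L)
  partial <- data.frame(start = 15L, end = 18L)
  cc <- compare_phi_spans(partial, gold)
  expect_identical(c(cc$tp, cc$fn, cc$fp), c(1L, 0L, 0L))
  disjoint <- data.frame(start = 30L, end = 35L)
  cd <- compare_phi_spans(disjoint, gold)
  expect_identical(c(cd$tp, cd$fn, cd$fp), c(0L, 1L, 1L))
  # overlapping spans within one list violate the contract
  bad <- data.frame(start = c(0L, 5L), end = c(8L, 9L))
  expect_error(compare_phi_spans(bad, gold), "overlapping")
})
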