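test_that("excluding a study type partitions the study list", {
  studies <- list(make_dich_study("s1", 5, 10, 5, 10, labels = "non_english"),
                  make_dich_study("s2", 6, 12, 5, 10),
                  make_dich_study("s3", 7, 14, 5, 10,
                                  labels = c("non_english", "dissertation")))
  rev <- review_record("r", "ARI", "RR", studies)
  reduced <- exclude_by_type(rev, "non_english")
  expect_equal(vapply(reduced, `[[`, character(1), "study_id"), "s2")
  # irrelevant label: identical list
  expect_identical(exclude_by_type(rev, "unpublished"), studies)
  # every study labelled: empty list
  expect_length(exclude_by_type(
    review_record("r2", "ARI", "RR", studies[c(1, 3)]), "non_english"), 0)
})

test_that("percent-lost arithmetic reproduces published counts", {
  expect_equal(round_half_away(percent_lost(29, 26), 1), 10.3)
  expect_equal(round_half_away(percent_lost(11306, 10899), 1), 3.6)
  expect_equal(percent_lost(7, 7), 0)
  expect_true(is.na(percent_lost(0, 0)))
  expect_error(percent_lost(3, 5), "exceeds")
})

test_that("percent changes are magnitude-only and computed on the natural scale", {
  expect_equal(round_half_away(percent_change_point(0.67, 0.68), 1), 1.5)
  expect_equal(round_half_away(percent_change_point(-1.25, -1.96), 1), 56.8)
  expect_equal(percent_change_point(0.5, 0.5), 0)
  expect_true(is.na(percent_change_point(0, 0.3)))
  expect_true(is.na(percent_change_point(0.5, NA)))

  expect_equal(round_half_away(
    percent_change_ci_width(c(0.50, 0.89), c(0.51, 0.91)), 1), 2.6)
  expect_equal(round_half_away(
    percent_change_ci_width(c(1.08, 1.81), c(1.05, 1.34)), 1), 60.3)
  expect_equal(percent_change_ci_width(c(0.1, 0.4), c(0.1, 0.4)), 0)
  expect_true(is.na(percent_change_ci_width(c(0.2, 0.2), c(0.1, 0.3))))
  expect_error(percent_change_ci_width(c(0.4, 0.1), c(0.1, 0.3)), "bound")

  # direction ignorance: simultaneous sign flip leaves the change alone
  set.seed(3)
  for (i in 1:50) {
    a <- rnorm(1); b <- rnorm(1)
    if (a == 0) next
    expect_equal(percent_change_point(a, b), percent_change_point(-a, -b))
  }
})

test_that("impact categories follow integer rounding of the percent change", {
  expect_equal(classify_change(10.1), "small")
  expect_equal(classify_change(15.7), "moderate")
  expect_equal(classify_change(23.1), "large")
  expect_equal(classify_change(0), "negligible")
  # boundary behaviour: round half away from zero, then 0-4 / 5-10 / 11-20 / 21+
  expect_equal(classify_change(4.49), "negligible")
  expect_equal(classify_change(4.5), "small")
  expect_equal(classify_change(10.49), "small")
  expect_equal(classify_change(10.5), "moderate")
  expect_equal(classify_change(20.49), "moderate")
  expect_equal(classify_change(20.5), "large")
  expect_equal(classify_change(NA), "not_estimable")
  expect_equal(classify_change(NA, all_removed = TRUE), "substantial")
  expect_equal(classify_change(250), "large")
})

test_that("significance flips compare CIs against the measure's null, bounds on the null not significant", {
  expect_equal(significance_flip(c(0.01, 0.07), c(0.00, 0.04), "RD"), "lost")
  expect_equal(significance_flip(c(-0.35, -0.13), c(-0.38, 0.00), "SMD"), "lost")
  expect_equal(significance_flip(c(0.50, 0.89), c(0.51, 0.91), "RR"), "none")
  expect_equal(significance_flip(c(0.82, 1.35), c(0.82, 1.35), "RR"), "none")
  expect_equal(significance_flip(c(0.9, 1.4), c(1.05, 1.4), "OR"), "gained")
  # exactly-on-the-null bound is not significant for ratio measures either
  expect_equal(significance_flip(c(1.00, 1.4), c(1.01, 1.4), "RR"), "gained")
  expect_equal(significance_flip(c(0.2, 0.9), NULL, "RR"), "undefined")
  expect_equal(significance_flip(c(0.2, 0.9), c(NA, 0.9), "RR"), "undefined")
})

test_that("run_impact composes the metrics of its two pooled analyses", {
  studies <- list(make_cont_study("s1", 1.0, 0.0),
                  make_cont_study("s2", 1.4, 0.1),
                  make_cont_study("s3", 0.3, 0.2, labels = "dissertation"))
  rev <- review_record("r", "DPLP", "MD", studies, model = "fixed")
  im <- run_impact(rev, "dissertation")

  with_p <- pool_studies(studies, "MD", "fixed")
  without_p <- pool_studies(studies[1:2], "MD", "fixed")
  expect_equal(im$with_result$point, with_p$point)
  expect_equal(im$without_result$point, without_p$point)
  expect_equal(im$pct_studies_lost, 100 / 3)
  expect_equal(im$pct_participants_lost, 100 / 3)
  expect_equal(im$pct_change_point,
               100 * abs(without_p$point - with_p$point) / abs(with_p$point))
  expect_equal(im$pct_change_ci_width,
               100 * abs((without_p$ci_high - without_p$ci_low) -
                           (with_p$ci_high - with_p$ci_low)) /
                 (with_p$ci_high - with_p$ci_low))
  expect_equal(im$category, classify_change(im$pct_change_point))
  expect_equal(im$significance_flip, significance_flip(with_p, without_p))

  # no study of the type: skip marker, not an error
  expect_null(run_impact(rev, "unpublished"))
})

test_that("a homogeneous labelled study leaves the estimate essentially unchanged", {
  studies <- list(make_dich_study("s1", 20, 100, 30, 100),
                  make_dich_study("s2", 20, 100, 30, 100),
                  make_dich_study("s3", 20, 100, 30, 100, labels = "non_english"))
  im <- run_impact(review_record("r", "ARI", "RR", studies), "non_english")
  expect_equal(im$pct_change_point, 0, tolerance = 1e-10)
  expect_equal(im$category, "negligible")
  expect_equal(im$significance_flip, "none")
})

test_that("removing every study yields a substantial, non-estimable impact", {
  studies <- list(make_dich_study("s1", 5, 10, 5, 10, labels = "unpublished"),
                  make_dich_study("s2", 6, 12, 5, 10, labels = "unpublished"))
  im <- run_impact(review_record("r", "ARI", "RR", studies), "unpublished")
  expect_false(im$without_result$estimable)
  expect_equal(im$category, "substantial")
  expect_equal(im$significance_flip, "undefined")
  expect_equal(im$pct_studies_lost, 100)
  expect_true(is.na(im$pct_change_point))
})

test_that("corpus-level impact runs bind one ordered row per review and label", {
  corpus <- list(
    review_record("B", "ARI", "RR",
                  list(make_dich_study("s1", 5, 10, 5, 10, labels = "non_english"),
                       make_dich_study("s2", 6, 12, 5, 10))),
    review_record("A", "ID", "MD",
                  list(make_cont_study("t1", 1, 0, labels = "unpublished"),
                       make_cont_study("t2", 1.2, 0, labels = "non_english"))))
  im <- run_corpus_impacts(corpus)
  expect_equal(nrow(im), 3)
  expect_equal(im$review_id, c("A", "B", "A"))
  expect_equal(im$label, c("non_english", "non_english", "unpublished"))
  expect_equal(nrow(run_corpus_impacts(list())), 0)
})
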