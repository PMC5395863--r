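small_config <- function(...) {
  generator_config(n_reviews_per_group = c(ARI = 8, ID = 6, DPLP = 6),
                   studies_per_review = list(size = 1, mu = 3), ...)
}

test_that("the generator is deterministic given a seed", {
  c1 <- generate_corpus(small_config(seed = 99))
  c2 <- generate_corpus(small_config(seed = 99))
  c3 <- generate_corpus(small_config(seed = 100))
  expect_identical(c1, c2)
  expect_false(identical(c1, c3))

  # and corpus files are byte-identical across runs for the same seed
  d1 <- file.path(tempdir(), "det1"); d2 <- file.path(tempdir(), "det2")
  write_corpus(c1, d1); write_corpus(c2, d2)
  expect_identical(readLines(file.path(d1, "studies.csv")),
                   readLines(file.path(d2, "studies.csv")))
})

test_that("empty and zero-prevalence configurations degenerate cleanly", {
  expect_length(generate_corpus(generator_config(
    n_reviews_per_group = c(ARI = 0), seed = 1)), 0)
  corp <- generate_corpus(small_config(
    label_prevalence = c(non_english = 0.3, unpublished = 0.1, dissertation = 0),
    seed = 5))
  labs <- unlist(lapply(corp, function(r) lapply(r$studies, `[[`, "labels")))
  expect_false("dissertation" %in% labs)
})

test_that("label prevalence is recovered within three binomial standard errors", {
  cfg <- generator_config(n_reviews_per_group = c(ARI = 150),
                          studies_per_review = list(size = 2, mu = 9),
                          seed = 202)
  corp <- generate_corpus(cfg)
  n_studies <- sum(vapply(corp, function(r) length(r$studies), integer(1)))
  for (lab in c("non_english", "unpublished", "dissertation")) {
    p <- cfg$label_prevalence[[lab]]
    n_lab <- sum(vapply(corp, function(r)
      sum(vapply(r$studies, function(s) lab %in% s$labels, logical(1))),
      integer(1)))
    se <- sqrt(p * (1 - p) / n_studies)
    expect_lt(abs(n_lab / n_studies - p), 3 * se + 1e-12)
  }
})

test_that("studies-per-review reproduces the target median and a heavy tail", {
  cfg <- generator_config(n_reviews_per_group = c(ARI = 400), seed = 77)
  corp <- generate_corpus(cfg)
  k <- vapply(corp, function(r) length(r$studies), integer(1))
  expect_true(median(k) %in% 2:4)
  expect_equal(min(k) >= 1, TRUE)
  expect_gt(quantile(k, 0.75), 15)  # wide IQR, right-skewed
})

test_that("invalid configurations are rejected naming the offending field", {
  expect_error(generator_config(label_prevalence = c(non_english = 1.5,
                                                     unpublished = 0, dissertation = 0)),
               "label_prevalence")
  expect_error(generator_config(searched_probability = c(non_english = 0.5)),
               "searched_probability")
  expect_error(generator_config(between_study_sd = -1), "between_study_sd")
  expect_error(generator_config(baseline_risk = 0), "baseline_risk")
  expect_error(generator_config(n_reviews_per_group = c(XX = 3)),
               "n_reviews_per_group")
  expect_error(generate_corpus(list()), "generator_config")
})

test_that("count fixtures round-trip through the corpus summary", {
  counts <- grey_search_counts()
  fx <- fixture_from_counts(counts)
  s <- summarize_corpus(fx)
  for (i in seq_len(nrow(counts))) {
    row <- counts[i, ]
    cell <- s[s$group == row$group & s$label == row$label, ]
    expect_equal(cell$n_reviews, row$n_reviews)
    expect_equal(cell$n_searched, row$n_searched)
    expect_equal(cell$n_included, row$n_included)
    expect_equal(cell$n_studies, row$n_studies)
    expect_equal(cell$n_studies_type, row$n_studies_type)
  }
})

test_that("inconsistent count tables are rejected", {
  counts <- grey_search_counts()
  bad <- counts
  bad$n_included[1] <- bad$n_searched[1] + 1
  expect_error(fixture_from_counts(bad), "included <= searched")
  bad2 <- counts
  bad2$n_studies_type[1] <- 0
  bad2$n_included[1] <- 3
  expect_error(fixture_from_counts(bad2), "typed")
  expect_error(fixture_from_counts(counts[, -1]), "columns")
})
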