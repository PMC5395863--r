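test_that("inverse-variance pooling reproduces hand arithmetic and identities", {
  # two effects 0 and 1, unit variances: point 0.5, SE sqrt(1/2)
  p <- pool_effects(list(effect_estimate(0, 1), effect_estimate(1, 1)),
                    "fixed", "MD")
  expect_equal(p$est, 0.5)
  expect_equal(p$se, sqrt(0.5))
  expect_equal(p$ci_low, 0.5 - 1.96 * sqrt(0.5))
  expect_equal(p$ci_high, 0.5 + 1.96 * sqrt(0.5))

  # single effect: pooled result is that effect
  single <- pool_effects(list(effect_estimate(0.7, 0.04)), "random", "MD")
  expect_equal(single$est, 0.7)
  expect_equal(single$se, 0.2)
  expect_equal(single$tau2, 0)

  # log-scale measures back-transform, and CI brackets the point
  pr <- pool_effects(list(effect_estimate(log(2), 0.1),
                          effect_estimate(log(1.5), 0.2)), "fixed", "RR")
  expect_equal(log(pr$point), pr$est)
  expect_true(pr$ci_low <= pr$point && pr$point <= pr$ci_high)

  # empty and all-non-estimable inputs flag, not raise
  expect_false(pool_effects(list(), "fixed", "RR")$estimable)
  expect_false(pool_effects(list(effect_estimate(estimable = FALSE)),
                            "fixed", "RR")$estimable)
})

test_that("identical effects give tau2 = 0 and random equals fixed", {
  e <- replicate(4, effect_estimate(0.3, 0.05), simplify = FALSE)
  fx <- pool_effects(e, "fixed", "MD")
  rn <- pool_effects(e, "random", "MD")
  expect_equal(rn$tau2, 0)
  expect_equal(rn$est, fx$est)
  expect_equal(rn$se, fx$se)
  expect_equal(fx$est, 0.3)
})

test_that("replication shrinks the CI without moving the point", {
  e1 <- effect_estimate(0.4, 0.1)
  p1 <- pool_effects(list(e1), "fixed", "MD")
  p5 <- pool_effects(replicate(5, e1, simplify = FALSE), "fixed", "MD")
  expect_equal(p5$est, p1$est)
  expect_lt(p5$ci_high - p5$ci_low, p1$ci_high - p1$ci_low)
})

test_that("adding a larger effect pulls the fixed-effect estimate toward it", {
  set.seed(7)
  for (i in 1:25) {
    e <- rand_effects(sample(2:5, 1))
    base <- pool_effects(e, "fixed", "MD")
    extra <- effect_estimate(base$est + runif(1, 0.1, 2), runif(1, 0.05, 2))
    grown <- pool_effects(c(e, list(extra)), "fixed", "MD")
    expect_gt(grown$est, base$est)
    expect_lt(grown$est, extra$value)
  }
})

test_that("Mantel-Haenszel pooling matches single-study and stratified oracles", {
  tb <- c(10, 40, 20, 45)
  one <- pool_mh(list(c(events_t = 10, total_t = 40, events_c = 20, total_c = 45)),
                 "RR")
  expect_equal(one$est, log((10 / 40) / (20 / 45)), tolerance = 1e-12)

  # two identical strata leave the estimate unchanged
  two <- pool_mh(rep(list(c(events_t = 10, total_t = 40, events_c = 20,
                            total_c = 45)), 2), "RR")
  expect_equal(two$est, one$est, tolerance = 1e-12)
  expect_lt(two$se, one$se)

  # two-stratum toy table against the brute-force stratified sums
  tabs <- list(c(events_t = 10, total_t = 50, events_c = 15, total_c = 50),
               c(events_t = 4, total_t = 40, events_c = 10, total_c = 45))
  raw <- list(c(10, 50, 15, 50), c(4, 40, 10, 45))
  for (m in c("RR", "OR", "RD")) {
    got <- pool_mh(tabs, m)
    want <- oracle_mh(raw, m)
    expect_equal(got$est, want$est, tolerance = 1e-12)
    expect_equal(got$se, want$se, tolerance = 1e-12)
  }

  # all double-zero strata: not estimable on the ratio scale
  dz <- list(c(events_t = 0, total_t = 10, events_c = 0, total_c = 10))
  expect_false(pool_mh(dz, "OR")$estimable)
  expect_true(pool_mh(dz, "RD")$estimable)
})

test_that("inverse-variance and MH results agree with metafor", {
  skip_if_not_installed("metafor")
  set.seed(11)
  y <- rnorm(6, 0.2, 0.4)
  v <- runif(6, 0.02, 0.3)
  eff <- lapply(seq_along(y), function(i) effect_estimate(y[i], v[i]))

  fe <- metafor::rma(yi = y, vi = v, method = "FE")
  expect_equal(pool_effects(eff, "fixed", "MD")$est, as.numeric(fe$beta),
               tolerance = 1e-10)
  dl <- metafor::rma(yi = y, vi = v, method = "DL")
  got <- pool_effects(eff, "random", "MD")
  expect_equal(got$est, as.numeric(dl$beta), tolerance = 1e-10)
  expect_equal(got$tau2, dl$tau2, tolerance = 1e-10)

  tabs <- replicate(4, rand_table(), simplify = FALSE)
  a <- sapply(tabs, `[`, 1); n1 <- sapply(tabs, `[`, 2)
  cc <- sapply(tabs, `[`, 3); n2 <- sapply(tabs, `[`, 4)
  as_list <- lapply(tabs, function(tb)
    c(events_t = tb[1], total_t = tb[2], events_c = tb[3], total_c = tb[4]))
  for (m in c("RR", "OR", "RD")) {
    fit <- metafor::rma.mh(measure = m, ai = a, bi = n1 - a, ci = cc,
                           di = n2 - cc)
    expect_equal(pool_mh(as_list, m)$est, as.numeric(fit$beta),
                 tolerance = 1e-10)
  }
})

test_that("review-level pooling dispatches on model and method", {
  studies <- list(make_dich_study("s1", 10, 50, 15, 50),
                  make_dich_study("s2", 4, 40, 10, 45))
  rev_iv <- review_record("r1", "ARI", "RR", studies, model = "fixed")
  rev_mh <- review_record("r2", "ARI", "RR", studies, model = "fixed",
                          method = "mantel_haenszel")
  expect_equal(pool_review(rev_mh)$method, "mantel_haenszel")
  expect_equal(pool_review(rev_iv)$method, "inverse_variance")
  expect_false(isTRUE(all.equal(pool_review(rev_mh)$est, pool_review(rev_iv)$est)))

  # random-effects always pools by inverse variance with DL tau2
  rev_mh_re <- review_record("r3", "ARI", "RR", studies, model = "random",
                             method = "mantel_haenszel")
  expect_equal(pool_review(rev_mh_re)$method, "inverse_variance")

  # precomputed effects pool as given
  pre <- review_record("r4", "other", "MD", list(
    study_record("p1", outcome_effect(0.2, 0.1), n_participants = 40),
    study_record("p2", outcome_effect(0.6, 0.1), n_participants = 60)))
  p <- pool_review(pre)
  expect_equal(p$est, 0.4)
  expect_equal(p$n_participants, 100L)

  expect_error(review_record("r5", "ARI", "MD", studies,
                             method = "mantel_haenszel"), "dichotomous")
})
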