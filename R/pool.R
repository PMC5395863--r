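pooled_result <- function(measure, model, method, est = NA_real_,
                          se = NA_real_, n_studies = 0L,
                          n_participants = NA_integer_, tau2 = NA_real_,
                          estimable = TRUE) {
  measure <- summary_measure(measure)
  if (estimable) {
    point <- if (measure$log_scale) exp(est) else est
    ci_low <- if (measure$log_scale) exp(est - Z95 * se) else est - Z95 * se
    ci_high <- if (measure$log_scale) exp(est + Z95 * se) else est + Z95 * se
  } else {
    point <- ci_low <- ci_high <- est <- se <- NA_real_
  }
  structure(list(measure = measure, model = model, method = method,
                 point = point, ci_low = ci_low, ci_high = ci_high,
                 est = est, se = se, n_studies = as.integer(n_studies),
                 n_participants = n_participants, tau2 = tau2,
                 estimable = estimable),
            class = "pooled_result")
}

#' @export
print.pooled_result <- function(x, ...) {
  if (!x$estimable) {
    cat(sprintf("<pooled %s: not estimable (%d studies)>\n",
                x$measure$code, x$n_studies))
    return(invisible(x))
  }
  cat(sprintf("<pooled %s (%s, %s): %s (95%% CI %s, %s); k = %d%s%s>\n",
              x$measure$code, x$model, x$method,
              fmt_num(x$point, 2), fmt_num(x$ci_low, 2), fmt_num(x$ci_high, 2),
              x$n_studies,
              if (!is.na(x$n_participants))
                sprintf(", n = %d", as.integer(x$n_participants)) else "",
              if (identical(x$model, "random"))
                sprintf(", tau2 = %s", fmt_num(x$tau2, 4)) else ""))
  invisible(x)
}

#' Inverse-variance pooling with optional DerSimonian-Laird tau-squared
#'
#' Pools per-study effects by inverse-variance weighting. Under the
#' random-effects model the DerSimonian-Laird moment estimator
#' `tau2 = max(0, (Q - df) / C)` is added to every study variance before
#' weighting (`Q` the fixed-effect heterogeneity statistic,
#' `C = sum(w) - sum(w^2)/sum(w)`). The 95% CI is `est +/- 1.96 * SE` on
#' the analysis scale, exponentiated for log-scale measures.
#'
#' Non-estimable effects are dropped; an empty (or all non-estimable)
#' effect list yields a flagged not-estimable result rather than an
#' error, so that downstream impact classification can represent the
#' "all studies removed" case.
#'
#' @param effects List of [effect_estimate()] objects.
#' @param model `"fixed"` or `"random"`.
#' @param measure Summary measure code or [summary_measure()].
#' @param n_participants Optional total participants, carried through.
#' @return A `pooled_result` with natural-scale `point`, `ci_low`,
#'   `ci_high`, analysis-scale `est` and `se`, `n_studies`, `tau2`
#'   (random model only) and an `estimable` flag.
#' @examples
#' e <- list(effect_estimate(0, 1), effect_estimate(1, 1))
#' pool_effects(e, "fixed", "MD")
#' @export
pool_effects <- function(effects, model = c("fixed", "random"), measure,
                         n_participants = NA_integer_) {
  model <- match.arg(model)
  measure <- summary_measure(measure)
  if (inherits(effects, "effect_estimate")) effects <- list(effects)
  stopifnot(is.list(effects))
  ok <- vapply(effects, function(e) inherits(e, "effect_estimate") && e$estimable,
               logical(1))
  if (!all(vapply(effects, inherits, logical(1), "effect_estimate")))
    stop_input("'effects' must be a list of effect_estimate objects")
  effects <- effects[ok]
  k <- length(effects)
  if (k == 0)
    return(pooled_result(measure, model, "inverse_variance",
                         n_participants = n_participants, estimable = FALSE))
  y <- vapply(effects, `[[`, numeric(1), "value")
  v <- vapply(effects, `[[`, numeric(1), "variance")
  w <- 1 / v
  est_fixed <- sum(w * y) / sum(w)
  tau2 <- NA_real_
  if (model == "random") {
    if (k == 1) {
      tau2 <- 0
    } else {
      q <- sum(w * (y - est_fixed)^2)
      cc <- sum(w) - sum(w^2) / sum(w)
      tau2 <- max(0, (q - (k - 1)) / cc)
    }
    w <- 1 / (v + tau2)
  }
  pooled_result(measure, model, "inverse_variance",
                est = sum(w * y) / sum(w), se = sqrt(1 / sum(w)),
                n_studies = k, n_participants = n_participants, tau2 = tau2)
}

#' Mantel-Haenszel fixed-effect pooling of 2x2 tables
#'
#' Stratified fixed-effect pooling for dichotomous outcomes using the
#' standard Mantel-Haenszel weights, with the Greenland-Robins variance
#' estimators for log `RR`/`OR` and the stratified binomial variance for
#' `RD`. Zero-cell tables are 0.5-corrected for `RR`/`OR` (all four
#' cells) and double-zero tables are excluded on ratio scales; `RD`
#' retains all tables.
#'
#' @param tables List of 2x2 tables; each a list/vector with elements
#'   `events_t`, `total_t`, `events_c`, `total_c`.
#' @param measure `"RR"`, `"OR"` or `"RD"`.
#' @param n_participants Optional total participants, carried through.
#' @return A `pooled_result` with `method = "mantel_haenszel"`.
#' @examples
#' tabs <- list(c(events_t = 10, total_t = 50, events_c = 15, total_c = 50),
#'              c(events_t = 4, total_t = 40, events_c = 10, total_c = 45))
#' pool_mh(tabs, "RR")
#' @export
pool_mh <- function(tables, measure, n_participants = NA_integer_) {
  measure <- summary_measure(measure)
  if (!is_dichotomous_measure(measure))
    stop_input("Mantel-Haenszel pooling requires a dichotomous measure, not '%s'",
               measure$code)
  stopifnot(is.list(tables), length(tables) >= 1)
  cells <- lapply(tables, function(tb) {
    tb <- as.list(tb)
    check_dich_arms(tb$events_t, tb$total_t, tb$events_c, tb$total_c)
  })
  a <- vapply(cells, `[[`, numeric(1), "a")
  n1 <- vapply(cells, `[[`, numeric(1), "n1")
  cc <- vapply(cells, `[[`, numeric(1), "c")
  n2 <- vapply(cells, `[[`, numeric(1), "n2")

  if (measure$code %in% c("RR", "OR")) {
    keep <- !(a == 0 & cc == 0)
    a <- a[keep]; n1 <- n1[keep]; cc <- cc[keep]; n2 <- n2[keep]
    if (length(a) == 0)
      return(pooled_result(measure, "fixed", "mantel_haenszel",
                           n_participants = n_participants, estimable = FALSE))
    b <- n1 - a; d <- n2 - cc
    zero <- a == 0 | b == 0 | cc == 0 | d == 0
    a <- a + 0.5 * zero; b <- b + 0.5 * zero
    cc <- cc + 0.5 * zero; d <- d + 0.5 * zero
    n1 <- n1 + 1 * zero; n2 <- n2 + 1 * zero
  } else {
    b <- n1 - a; d <- n2 - cc
  }
  nn <- n1 + n2
  k <- length(a)

  if (measure$code == "RR") {
    sr <- sum(a * n2 / nn); ss <- sum(cc * n1 / nn)
    if (sr == 0 || ss == 0)
      return(pooled_result(measure, "fixed", "mantel_haenszel",
                           n_participants = n_participants, estimable = FALSE))
    p <- sum((n1 * n2 * (a + cc) - a * cc * nn) / nn^2)
    pooled_result(measure, "fixed", "mantel_haenszel",
                  est = log(sr / ss), se = sqrt(p / (sr * ss)),
                  n_studies = k, n_participants = n_participants)
  } else if (measure$code == "OR") {
    r <- a * d / nn; s <- b * cc / nn
    if (sum(r) == 0 || sum(s) == 0)
      return(pooled_result(measure, "fixed", "mantel_haenszel",
                           n_participants = n_participants, estimable = FALSE))
    p <- (a + d) / nn; q <- (b + cc) / nn
    vr <- sum(p * r) / (2 * sum(r)^2) +
      sum(p * s + q * r) / (2 * sum(r) * sum(s)) +
      sum(q * s) / (2 * sum(s)^2)
    pooled_result(measure, "fixed", "mantel_haenszel",
                  est = log(sum(r) / sum(s)), se = sqrt(vr),
                  n_studies = k, n_participants = n_participants)
  } else { # RD
    w <- n1 * n2 / nn
    if (sum(w) == 0)
      return(pooled_result(measure, "fixed", "mantel_haenszel",
                           n_participants = n_participants, estimable = FALSE))
    est <- sum(w * (a / n1 - cc / n2)) / sum(w)
    vr <- sum((a * b * n2^3 + cc * d * n1^3) / (n1 * n2 * nn^2)) / sum(w)^2
    pooled_result(measure, "fixed", "mantel_haenszel",
                  est = est, se = sqrt(vr),
                  n_studies = k, n_participants = n_participants)
  }
}
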