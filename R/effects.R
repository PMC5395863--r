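#' Per-study effect estimate
#'
#' Container for a single study's effect on the analysis scale (log
#' scale for RR/OR, identity scale otherwise). Non-estimable effects
#' (e.g. a double-zero 2x2 table on a ratio scale) carry no value and
#' are dropped from pooling.
#'
#' @param value Effect on the analysis scale.
#' @param variance Sampling variance of `value`; must be positive when
#'   `estimable` is `TRUE`.
#' @param estimable Logical flag.
#' @return An object of class `effect_estimate`.
#' @export
effect_estimate <- function(value, variance, estimable = TRUE) {
  if (!estimable)
    return(structure(list(value = NA_real_, variance = NA_real_,
                          estimable = FALSE), class = "effect_estimate"))
  value <- check_number(value, "value")
  variance <- check_number(variance, "variance")
  if (variance <= 0) stop_input("'variance' must be > 0 (got %g)", variance)
  structure(list(value = value, variance = variance, estimable = TRUE),
            class = "effect_estimate")
}

#' @export
print.effect_estimate <- function(x, ...) {
  if (x$estimable)
    cat(sprintf("<effect %.4f (var %.4f)>\n", x$value, x$variance))
  else cat("<effect not estimable>\n")
  invisible(x)
}

check_dich_arms <- function(events_t, total_t, events_c, total_c) {
  events_t <- check_count(events_t, "events_t")
  total_t  <- check_count(total_t, "total_t", min = 1)
  events_c <- check_count(events_c, "events_c")
  total_c  <- check_count(total_c, "total_c", min = 1)
  if (events_t > total_t || events_c > total_c)
    stop_input("events exceed arm total (%d/%d vs %d/%d)",
               events_t, total_t, events_c, total_c)
  list(a = events_t, n1 = total_t, c = events_c, n2 = total_c)
}

#' Effect estimate from a 2x2 table
#'
#' Computes a single study's effect for a dichotomous outcome. `RR` and
#' `OR` are returned on the log scale with the standard large-sample
#' variances; `RD` on the identity scale with the binomial variance.
#'
#' Zero cells: when any of the four cells is zero and the measure is a
#' ratio (`RR`/`OR`), 0.5 is added to all four cells (the usual
#' continuity correction). A table with zero events in both arms is not
#' estimable on a ratio scale; for `RD` such a table contributes an
#' effect of 0 whose variance is computed from the 0.5-corrected cells
#' (the uncorrected variance would be zero and the study could not be
#' weighted).
#'
#' @param events_t,total_t Events and sample size, treatment arm.
#' @param events_c,total_c Events and sample size, control arm.
#' @param measure `"RR"`, `"OR"` or `"RD"` (or a [summary_measure()]).
#' @return An [effect_estimate()].
#' @examples
#' effect_dichotomous(5, 10, 5, 10, "RR")   # log RR 0, variance 0.2
#' effect_dichotomous(0, 10, 5, 10, "RR")   # continuity-corrected
#' effect_dichotomous(0, 10, 0, 10, "OR")   # not estimable
#' @export
effect_dichotomous <- function(events_t, total_t, events_c, total_c, measure) {
  measure <- summary_measure(measure)
  if (!is_dichotomous_measure(measure))
    stop_input("measure '%s' does not apply to dichotomous outcomes", measure$code)
  arms <- check_dich_arms(events_t, total_t, events_c, total_c)
  a <- arms$a; n1 <- arms$n1; c_ <- arms$c; n2 <- arms$n2
  b <- n1 - a; d <- n2 - c_
  double_zero <- (a == 0 && c_ == 0)

  if (measure$code %in% c("RR", "OR")) {
    if (double_zero) return(effect_estimate(estimable = FALSE))
    if (a == 0 || b == 0 || c_ == 0 || d == 0) {
      a <- a + 0.5; b <- b + 0.5; c_ <- c_ + 0.5; d <- d + 0.5
      n1 <- n1 + 1; n2 <- n2 + 1
    }
    if (measure$code == "RR") {
      effect_estimate(log((a / n1) / (c_ / n2)),
                      1 / a - 1 / n1 + 1 / c_ - 1 / n2)
    } else {
      effect_estimate(log((a * d) / (b * c_)),
                      1 / a + 1 / b + 1 / c_ + 1 / d)
    }
  } else { # RD
    est <- a / n1 - c_ / n2
    vi <- a * b / n1^3 + c_ * d / n2^3
    if (vi == 0) { # all-zero or all-events arms: corrected-cell variance
      a2 <- a + 0.5; b2 <- b + 0.5; c2 <- c_ + 0.5; d2 <- d + 0.5
      m1 <- n1 + 1; m2 <- n2 + 1
      vi <- a2 * b2 / m1^3 + c2 * d2 / m2^3
      if (double_zero) est <- 0
    }
    effect_estimate(est, vi)
  }
}

#' Effect estimate from continuous arm summaries
#'
#' `MD` is the raw mean difference with variance
#' `sd_t^2/n_t + sd_c^2/n_c`. `SMD` is the standardized mean difference
#' using the pooled standard deviation and the small-sample (Hedges)
#' correction `1 - 3/(4N - 9)` with `N = n_t + n_c`; its variance is the
#' usual approximation `N/(n_t n_c) + g^2 / (2 (N - 3.94))`.
#'
#' @param mean_t,sd_t,n_t Treatment-arm mean, SD (> 0) and size (>= 2).
#' @param mean_c,sd_c,n_c Control-arm mean, SD (> 0) and size (>= 2).
#' @param measure `"MD"` or `"SMD"` (or a [summary_measure()]).
#' @param hedges Apply the small-sample correction for `SMD`
#'   (default `TRUE`; set `FALSE` for Cohen's d).
#' @return An [effect_estimate()].
#' @examples
#' effect_continuous(10, 2, 20, 8, 2, 20, "MD")  # MD 2, variance 0.4
#' @export
effect_continuous <- function(mean_t, sd_t, n_t, mean_c, sd_c, n_c, measure,
                              hedges = TRUE) {
  measure <- summary_measure(measure)
  if (!(measure$code %in% c("MD", "SMD")))
    stop_input("measure '%s' does not apply to continuous outcomes", measure$code)
  mean_t <- check_number(mean_t, "mean_t"); mean_c <- check_number(mean_c, "mean_c")
  sd_t <- check_number(sd_t, "sd_t"); sd_c <- check_number(sd_c, "sd_c")
  n_t <- check_count(n_t, "n_t", min = 2); n_c <- check_count(n_c, "n_c", min = 2)
  if (sd_t <= 0 || sd_c <= 0) stop_input("arm standard deviations must be > 0")

  if (measure$code == "MD") {
    effect_estimate(mean_t - mean_c, sd_t^2 / n_t + sd_c^2 / n_c)
  } else {
    N <- n_t + n_c
    sp <- sqrt(((n_t - 1) * sd_t^2 + (n_c - 1) * sd_c^2) / (N - 2))
    d <- (mean_t - mean_c) / sp
    j <- if (hedges) 1 - 3 / (4 * N - 9) else 1
    g <- j * d
    effect_estimate(g, N / (n_t * n_c) + g^2 / (2 * (N - 3.94)))
  }
}
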