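IMPACT_CATEGORIES <- c("negligible", "small", "moderate", "large",
                       "substantial", "not_estimable")

#' Drop studies carrying a grey-literature label
#'
#' @param review A [review_record()].
#' @param label One of `"non_english"`, `"unpublished"`, `"dissertation"`.
#' @return The review's studies that do not carry `label`, in their
#'   original order; possibly empty.
#' @export
exclude_by_type <- function(review, label) {
  stopifnot(inherits(review, "review_record"))
  label <- match.arg(label, LABELS)
  Filter(function(s) !has_label(s, label), review$studies)
}

#' Percent of studies (or participants) lost to an exclusion
#'
#' @param count_with Count in the full analysis (> 0).
#' @param count_without Count after exclusion (`<= count_with`).
#' @return `100 * (count_with - count_without) / count_with`, full
#'   precision (reporting rounds to one decimal); `NA` when
#'   `count_with` is zero or missing.
#' @examples
#' percent_lost(29, 26)  # 10.34...
#' @export
percent_lost <- function(count_with, count_without) {
  if (is.na(count_with) || is.na(count_without)) return(NA_real_)
  if (count_without > count_with)
    stop_input("count_without (%g) exceeds count_with (%g)",
               count_without, count_with)
  if (count_with == 0) return(NA_real_)
  100 * (count_with - count_without) / count_with
}

#' Magnitude-only percent change in the point estimate
#'
#' Both estimates are taken on the natural (reported) scale. The
#' direction of effect is ignored: only magnitudes are compared, so the
#' result is invariant under a simultaneous sign flip of both
#' estimates. A zero full-analysis estimate leaves the relative change
#' undefined and returns `NA`.
#'
#' @param with_point Pooled point estimate with all studies.
#' @param without_point Pooled point estimate after exclusion.
#' @return `100 * |without - with| / |with|`, or `NA` when not
#'   estimable.
#' @examples
#' percent_change_point(0.67, 0.68)   # 1.49...
#' percent_change_point(-1.25, -1.96) # 56.8
#' @export
percent_change_point <- function(with_point, without_point) {
  if (is.na(with_point) || is.na(without_point)) return(NA_real_)
  if (with_point == 0) return(NA_real_)
  100 * abs(without_point - with_point) / abs(with_point)
}

#' Percent change in confidence-interval width
#'
#' Widths are `high - low` on the natural scale (ratio-measure CIs are
#' compared after back-transformation, not on the log scale).
#'
#' @param with_ci,without_ci Length-2 numeric vectors `c(low, high)` on
#'   the natural scale.
#' @return `100 * |width_without - width_with| / width_with`, or `NA`
#'   when either interval is missing or the full-analysis width is zero.
#' @examples
#' percent_change_ci_width(c(0.50, 0.89), c(0.51, 0.91))  # 2.56...
#' @export
percent_change_ci_width <- function(with_ci, without_ci) {
  if (length(with_ci) != 2 || length(without_ci) != 2)
    stop_input("confidence intervals must be length-2 c(low, high)")
  if (anyNA(with_ci) || anyNA(without_ci)) return(NA_real_)
  if (with_ci[1] > with_ci[2] || without_ci[1] > without_ci[2])
    stop_input("interval low bound exceeds high bound")
  ww <- with_ci[2] - with_ci[1]
  if (ww == 0) return(NA_real_)
  100 * abs((without_ci[2] - without_ci[1]) - ww) / ww
}

#' Classify the change in point estimate
#'
#' The percent change is rounded to the nearest integer (half away from
#' zero) and mapped to: 0-4 `negligible`, 5-10 `small`, 11-20
#' `moderate`, 21+ `large`. `substantial` is reserved for the case
#' where every study carried the excluded label, so no reduced estimate
#' exists; a non-estimable percent change otherwise maps to
#' `not_estimable`.
#'
#' @param pct_change_point Percent change, or `NA`.
#' @param all_removed Were all studies removed by the exclusion?
#' @return A single category string.
#' @examples
#' classify_change(10.1)  # small
#' classify_change(23.1)  # large
#' classify_change(NA, all_removed = TRUE)  # substantial
#' @export
classify_change <- function(pct_change_point, all_removed = FALSE) {
  if (isTRUE(all_removed)) return("substantial")
  if (is.na(pct_change_point)) return("not_estimable")
  r <- round_half_away(abs(pct_change_point))
  if (r < 5) "negligible" else if (r <= 10) "small"
  else if (r <= 20) "moderate" else "large"
}

#' Change in statistical significance between two pooled results
#'
#' A result is significant iff its 95% CI strictly excludes the
#' measure's null value (1 for ratio measures, 0 for difference
#' measures); a bound exactly on the null counts as not significant.
#'
#' @param with_result,without_result `pooled_result` objects (or
#'   length-2 natural-scale CIs when `measure` is supplied).
#' @param measure Required when passing bare CIs; ignored otherwise.
#' @return `"none"`, `"lost"` (significant became not), `"gained"`, or
#'   `"undefined"` when either result is not estimable.
#' @examples
#' significance_flip(c(0.01, 0.07), c(0.00, 0.04), "RD")  # lost
#' @export
significance_flip <- function(with_result, without_result, measure = NULL) {
  ci_of <- function(x) {
    if (inherits(x, "pooled_result")) {
      if (!x$estimable) return(NULL)
      c(x$ci_low, x$ci_high)
    } else {
      if (length(x) != 2 || anyNA(x))
        return(NULL)
      as.numeric(x)
    }
  }
  if (inherits(with_result, "pooled_result")) measure <- with_result$measure
  if (is.null(measure))
    stop_input("'measure' is required when passing bare confidence intervals")
  null_value <- summary_measure(measure)$null_value
  wi <- ci_of(with_result); wo <- ci_of(without_result)
  if (is.null(wi) || is.null(wo)) return("undefined")
  sig <- function(ci) ci[1] > null_value || ci[2] < null_value
  s1 <- sig(wi); s2 <- sig(wo)
  if (s1 && !s2) "lost" else if (!s1 && s2) "gained" else "none"
}

#' Re-analyse one review without one study type
#'
#' Composes the full with/without comparison for one review and one
#' grey-literature label: the reduced study set is pooled with the
#' review's own summary measure, model and method, and the change is
#' quantified (percent studies and participants lost, magnitude-only
#' percent change in point estimate and CI width on the natural scale)
#' and classified.
#'
#' Reviews containing no study with the label are skipped — `NULL` is
#' returned, mirroring the analysis set of a corpus run ("at least one
#' study of the type"), rather than an error.
#'
#' @param review A [review_record()].
#' @param label Study-type label.
#' @return An object of class `impact_metrics` (see
#'   [as.data.frame.impact_metrics()]), or `NULL` if the review has no
#'   study of the type.
#' @export
run_impact <- function(review, label) {
  stopifnot(inherits(review, "review_record"))
  label <- match.arg(label, LABELS)
  labelled <- vapply(review$studies, has_label, logical(1), label)
  if (!any(labelled)) return(NULL)
  reduced <- exclude_by_type(review, label)
  with_result <- pool_review(review)
  without_result <- pool_studies(reduced, review$measure, review$model,
                                 review$method)
  all_removed <- length(reduced) == 0
  n_with <- length(review$studies)
  n_without <- length(reduced)
  p_with <- review_participants(review$studies)
  p_without <- if (length(reduced)) review_participants(reduced) else 0L
  pcp <- percent_change_point(with_result$point, without_result$point)
  pcw <- percent_change_ci_width(c(with_result$ci_low, with_result$ci_high),
                                 c(without_result$ci_low, without_result$ci_high))
  structure(list(
    review_id = review$review_id,
    group = review$group,
    label = label,
    with_result = with_result,
    without_result = without_result,
    n_studies_with = n_with,
    n_studies_without = n_without,
    pct_studies_lost = percent_lost(n_with, n_without),
    n_participants_with = p_with,
    n_participants_without = p_without,
    pct_participants_lost = percent_lost(p_with, p_without),
    pct_change_point = pcp,
    pct_change_ci_width = pcw,
    category = classify_change(pcp, all_removed = all_removed),
    significance_flip = significance_flip(with_result, without_result)
  ), class = "impact_metrics")
}

#' @export
print.impact_metrics <- function(x, ...) {
  cat(sprintf("<impact of removing %s from %s: %s (%s%% change), flip: %s>\n",
              x$label, x$review_id, x$category,
              fmt_num(x$pct_change_point, 1), x$significance_flip))
  invisible(x)
}

fmt_pooled <- function(p) {
  if (!p$estimable) return("NA")
  sprintf("%s (%s, %s)", fmt_num(p$point, 2), fmt_num(p$ci_low, 2),
          fmt_num(p$ci_high, 2))
}

#' Flatten impact metrics to a data frame row
#'
#' @param x An `impact_metrics` object from [run_impact()].
#' @param row.names,optional,... Passed through (unused).
#' @return One-row data frame with identifiers, counts, full-precision
#'   percentages, formatted pooled estimates, category and
#'   significance-flip flag.
#' @export
as.data.frame.impact_metrics <- function(x, row.names = NULL,
                                         optional = FALSE, ...) {
  data.frame(
    review_id = x$review_id, group = x$group, label = x$label,
    measure = x$with_result$measure$code,
    n_studies_with = x$n_studies_with,
    n_studies_without = x$n_studies_without,
    pct_studies_lost = x$pct_studies_lost,
    n_participants_with = x$n_participants_with,
    n_participants_without = x$n_participants_without,
    pct_participants_lost = x$pct_participants_lost,
    estimate_with = fmt_pooled(x$with_result),
    estimate_without = fmt_pooled(x$without_result),
    point_with = x$with_result$point,
    point_without = x$without_result$point,
    pct_change_point = x$pct_change_point,
    pct_change_ci_width = x$pct_change_ci_width,
    category = x$category,
    significance_flip = x$significance_flip,
    stringsAsFactors = FALSE
  )
}

#' Run the impact analysis over a whole corpus
#'
#' Applies [run_impact()] to every review x label combination where the
#' review includes at least one study of the type, and binds the
#' results into one data frame ordered by label, then review id.
#'
#' @param corpus List of [review_record()] objects.
#' @param labels Labels to analyse (default all three).
#' @return A data frame (possibly zero rows) with one row per
#'   review x label, columns as in [as.data.frame.impact_metrics()].
#' @export
run_corpus_impacts <- function(corpus, labels = LABELS) {
  stopifnot(is.list(corpus))
  rows <- list()
  for (label in labels) {
    for (review in corpus) {
      im <- run_impact(review, label)
      if (!is.null(im)) rows[[length(rows) + 1]] <- as.data.frame(im)
    }
  }
  if (length(rows) == 0) {
    out <- as.data.frame(run_impact(
      review_record("r", "other", "MD",
                    list(study_record("s", outcome_continuous(1, 1, 5, 0, 1, 5),
                                      labels = "non_english"))),
      "non_english"))
    return(out[0, , drop = FALSE])
  }
  out <- do.call(rbind, rows)
  out[order(match(out$label, LABELS), out$review_id), , drop = FALSE]
}
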