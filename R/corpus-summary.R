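#' Summarize searching and inclusion of grey-literature study types
#'
#' For each review group and overall, and for each study type, counts:
#' the reviews whose search explicitly covered the type (percent of all
#' reviews in the group), the reviews that included at least one study
#' of the type (percent of the reviews that searched for it — note the
#' denominator), and the included studies of the type (percent of all
#' studies included across the group's reviews). Percentages are
#' rounded to one decimal; the underlying counts are exact.
#'
#' @param corpus List of [review_record()] objects.
#' @return A data frame of class `corpus_summary` with one row per
#'   label x group plus a `Total` row per label; columns `label`,
#'   `group`, `n_reviews`, `n_searched`, `pct_searched`, `n_included`,
#'   `pct_included`, `n_studies`, `n_studies_type`, `pct_studies_type`.
#'   Empty corpus gives a zero-row frame.
#' @export
summarize_corpus <- function(corpus) {
  stopifnot(is.list(corpus))
  cols <- c("label", "group", "n_reviews", "n_searched", "pct_searched",
            "n_included", "pct_included", "n_studies", "n_studies_type",
            "pct_studies_type")
  if (length(corpus) == 0) {
    out <- data.frame(label = character(), group = character(),
                      n_reviews = integer(), n_searched = integer(),
                      pct_searched = numeric(), n_included = integer(),
                      pct_included = numeric(), n_studies = integer(),
                      n_studies_type = integer(), pct_studies_type = numeric(),
                      stringsAsFactors = FALSE)
    class(out) <- c("corpus_summary", "data.frame")
    return(out)
  }
  stopifnot(all(vapply(corpus, inherits, logical(1), "review_record")))
  groups <- intersect(GROUPS, unique(vapply(corpus, `[[`, character(1), "group")))
  pct <- function(num, den) {
    ifelse(is.na(den) | den == 0, NA_real_, round_half_away(100 * num / den, 1))
  }
  cell <- function(reviews, label, group) {
    searched <- vapply(reviews, function(r) isTRUE(r$searched[[label]]), logical(1))
    included <- vapply(reviews, function(r)
      any(vapply(r$studies, has_label, logical(1), label)), logical(1))
    n_studies <- sum(vapply(reviews, function(r) length(r$studies), integer(1)))
    n_type <- sum(vapply(reviews, function(r)
      sum(vapply(r$studies, has_label, logical(1), label)), integer(1)))
    data.frame(label = label, group = group,
               n_reviews = length(reviews),
               n_searched = sum(searched),
               pct_searched = pct(sum(searched), length(reviews)),
               n_included = sum(included),
               pct_included = pct(sum(included), sum(searched)),
               n_studies = n_studies,
               n_studies_type = n_type,
               pct_studies_type = pct(n_type, n_studies),
               stringsAsFactors = FALSE)
  }
  rows <- list()
  for (label in LABELS) {
    for (g in groups) {
      in_g <- Filter(function(r) r$group == g, corpus)
      rows[[length(rows) + 1]] <- cell(in_g, label, g)
    }
    rows[[length(rows) + 1]] <- cell(corpus, label, "Total")
  }
  out <- do.call(rbind, rows)[, cols]
  class(out) <- c("corpus_summary", "data.frame")
  out
}

#' Corpus descriptive statistics
#'
#' Median and interquartile range of publication year, studies per
#' review, and participants per review, using the inclusive
#' linear-interpolation quartile convention ([stats::quantile()] type
#' 7). Year statistics are omitted when all years are missing.
#'
#' @param corpus Non-empty list of [review_record()] objects.
#' @return A data frame with columns `quantity`, `median`, `q1`, `q3`.
#' @export
describe_corpus <- function(corpus) {
  stopifnot(is.list(corpus), length(corpus) > 0)
  q <- function(x) stats::quantile(x, c(0.5, 0.25, 0.75), names = FALSE, type = 7)
  studies <- vapply(corpus, function(r) length(r$studies), integer(1))
  participants <- vapply(corpus, function(r)
    as.numeric(review_participants(r$studies)), numeric(1))
  rows <- list()
  years <- vapply(corpus, function(r) as.numeric(r$year %||% NA), numeric(1))
  if (any(!is.na(years))) {
    v <- q(years[!is.na(years)])
    rows[[length(rows) + 1]] <- data.frame(quantity = "year", median = v[1],
                                           q1 = v[2], q3 = v[3])
  }
  v <- q(studies)
  rows[[length(rows) + 1]] <- data.frame(quantity = "studies_per_review",
                                         median = v[1], q1 = v[2], q3 = v[3])
  pp <- participants[!is.na(participants)]
  if (length(pp)) {
    v <- q(pp)
    rows[[length(rows) + 1]] <- data.frame(quantity = "participants_per_review",
                                           median = v[1], q1 = v[2], q3 = v[3])
  }
  do.call(rbind, rows)
}
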