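#' Study outcome payloads
#'
#' A study carries exactly one outcome representation: arm-level
#' dichotomous counts, arm-level continuous summaries, or a precomputed
#' effect with its variance on the analysis scale (log scale for ratio
#' measures).
#'
#' @param events_t,total_t,events_c,total_c Dichotomous arm counts.
#' @param mean_t,sd_t,n_t,mean_c,sd_c,n_c Continuous arm summaries.
#' @param effect,variance Precomputed effect (analysis scale) and its
#'   sampling variance.
#' @return A list with a `kind` field (`"dichotomous"`, `"continuous"`
#'   or `"effect"`).
#' @name outcomes
NULL

#' @rdname outcomes
#' @export
outcome_dichotomous <- function(events_t, total_t, events_c, total_c) {
  arms <- check_dich_arms(events_t, total_t, events_c, total_c)
  list(kind = "dichotomous", events_t = arms$a, total_t = arms$n1,
       events_c = arms$c, total_c = arms$n2)
}

#' @rdname outcomes
#' @export
outcome_continuous <- function(mean_t, sd_t, n_t, mean_c, sd_c, n_c) {
  if (check_number(sd_t, "sd_t") <= 0 || check_number(sd_c, "sd_c") <= 0)
    stop_input("arm standard deviations must be > 0")
  list(kind = "continuous",
       mean_t = check_number(mean_t, "mean_t"), sd_t = sd_t,
       n_t = check_count(n_t, "n_t", min = 2),
       mean_c = check_number(mean_c, "mean_c"), sd_c = sd_c,
       n_c = check_count(n_c, "n_c", min = 2))
}

#' @rdname outcomes
#' @export
outcome_effect <- function(effect, variance) {
  effect <- check_number(effect, "effect")
  variance <- check_number(variance, "variance")
  if (variance <= 0) stop_input("'variance' must be > 0")
  list(kind = "effect", effect = effect, variance = variance)
}

#' One included study
#'
#' @param study_id Identifier, unique within its review.
#' @param outcome One of the [outcomes] payloads.
#' @param labels Character vector drawn from `"non_english"`,
#'   `"unpublished"`, `"dissertation"`; a study may carry zero, one or
#'   several labels.
#' @param n_participants Participant count; defaults to the sum of arm
#'   totals when arm-level data are present.
#' @param language Optional free-text language of publication.
#' @return An object of class `study_record`.
#' @export
study_record <- function(study_id, outcome, labels = character(),
                         n_participants = NULL, language = NA_character_) {
  stopifnot(is.character(study_id), length(study_id) == 1)
  if (!is.list(outcome) || is.null(outcome$kind) ||
      !(outcome$kind %in% c("dichotomous", "continuous", "effect")))
    stop_input("study '%s': 'outcome' must be built with outcome_*()", study_id)
  labels <- unique(as.character(labels))
  bad <- setdiff(labels, LABELS)
  if (length(bad))
    stop_input("study '%s': unknown label(s) %s", study_id,
               paste(sQuote(bad), collapse = ", "))
  if (is.null(n_participants)) {
    n_participants <- switch(outcome$kind,
      dichotomous = outcome$total_t + outcome$total_c,
      continuous = outcome$n_t + outcome$n_c,
      effect = NA_integer_)
  }
  if (!is.na(n_participants))
    n_participants <- check_count(n_participants, "n_participants")
  structure(list(study_id = study_id, labels = labels,
                 n_participants = n_participants, outcome = outcome,
                 language = language),
            class = "study_record")
}

has_label <- function(study, label) label %in% study$labels

#' One systematic review's primary meta-analysis
#'
#' @param review_id Identifier, unique within a corpus.
#' @param group Review group: `"ARI"`, `"ID"`, `"DPLP"` or `"other"`.
#' @param measure Summary measure code or [summary_measure()].
#' @param studies Non-empty list of [study_record()] objects.
#' @param model `"fixed"` or `"random"` (DerSimonian-Laird).
#' @param method `"inverse_variance"` or `"mantel_haenszel"`. The
#'   Mantel-Haenszel method applies to the fixed-effect model with
#'   dichotomous outcomes; random-effects pooling always uses
#'   inverse-variance weights with DL tau-squared.
#' @param searched Named logical vector: did the review's search
#'   explicitly cover each study type? Missing labels default to `FALSE`.
#' @param year Publication year (optional).
#' @return An object of class `review_record`.
#' @export
review_record <- function(review_id, group, measure, studies,
                          model = "fixed", method = "inverse_variance",
                          searched = c(non_english = FALSE, unpublished = FALSE,
                                       dissertation = FALSE),
                          year = NA_integer_) {
  stopifnot(is.character(review_id), length(review_id) == 1)
  if (!(group %in% GROUPS))
    stop_input("review '%s': unknown group '%s'", review_id, group)
  measure <- summary_measure(measure)
  if (!(model %in% MODELS))
    stop_input("review '%s': unknown model '%s'", review_id, model)
  if (!(method %in% METHODS))
    stop_input("review '%s': unknown method '%s'", review_id, method)
  if (!is.list(studies) || length(studies) == 0 ||
      !all(vapply(studies, inherits, logical(1), "study_record")))
    stop_input("review '%s': 'studies' must be a non-empty list of study_record",
               review_id)
  ids <- vapply(studies, `[[`, character(1), "study_id")
  if (anyDuplicated(ids))
    stop_input("review '%s': duplicated study_id", review_id)
  if (method == "mantel_haenszel") {
    kinds <- vapply(studies, function(s) s$outcome$kind, character(1))
    if (!is_dichotomous_measure(measure) || any(kinds != "dichotomous"))
      stop_input("review '%s': mantel_haenszel requires dichotomous arm data",
                 review_id)
  }
  flags <- stats::setNames(rep(FALSE, length(LABELS)), LABELS)
  flags[names(searched)] <- as.logical(searched)
  structure(list(review_id = review_id, group = group, measure = measure,
                 model = model, method = method, searched = flags,
                 studies = studies,
                 year = if (is.na(year)) NA_integer_ else check_count(year, "year")),
            class = "review_record")
}

#' @export
print.review_record <- function(x, ...) {
  cat(sprintf("<review %s [%s]: %d studies, %s, %s model (%s)>\n",
              x$review_id, x$group, length(x$studies), x$measure$code,
              x$model, x$method))
  invisible(x)
}

study_effect <- function(study, measure) {
  o <- study$outcome
  switch(o$kind,
    dichotomous = effect_dichotomous(o$events_t, o$total_t, o$events_c,
                                     o$total_c, measure),
    continuous = effect_continuous(o$mean_t, o$sd_t, o$n_t, o$mean_c, o$sd_c,
                                   o$n_c, measure),
    effect = effect_estimate(o$effect, o$variance))
}

review_participants <- function(studies) {
  n <- vapply(studies, `[[`, numeric(1), "n_participants")
  if (all(is.na(n))) NA_integer_ else as.integer(sum(n, na.rm = TRUE))
}

#' Pool a set of studies with a review's original methods
#'
#' Recomputes a pooled result for an arbitrary subset of a review's
#' studies using the review's own summary measure, model and pooling
#' method — the operation behind every with/without comparison. An empty
#' subset yields a flagged not-estimable result.
#'
#' @param studies List of [study_record()] objects (may be empty).
#' @param measure,model,method As in [review_record()].
#' @return A `pooled_result`.
#' @export
pool_studies <- function(studies, measure, model = "fixed",
                         method = "inverse_variance") {
  measure <- summary_measure(measure)
  n_part <- if (length(studies)) review_participants(studies) else NA_integer_
  if (length(studies) == 0)
    return(pooled_result(measure, model, method, estimable = FALSE))
  if (method == "mantel_haenszel" && model == "fixed") {
    tables <- lapply(studies, function(s) s$outcome[c("events_t", "total_t",
                                                      "events_c", "total_c")])
    return(pool_mh(tables, measure, n_participants = n_part))
  }
  effects <- lapply(studies, study_effect, measure = measure)
  pool_effects(effects, model = model, measure = measure,
               n_participants = n_part)
}

#' @rdname pool_studies
#' @param review A [review_record()].
#' @export
pool_review <- function(review) {
  stopifnot(inherits(review, "review_record"))
  pool_studies(review$studies, review$measure, review$model, review$method)
}
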