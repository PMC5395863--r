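NONENGLISH_LANGUAGES <- c(French = 0.32, Spanish = 0.21, Italian = 0.18,
                          German = 0.14, Chinese = 0.07, Turkish = 0.04,
                          Swedish = 0.04)

#' Configuration for the synthetic review-corpus generator
#'
#' Defaults emulate the structure of a child-health Cochrane corpus:
#' three review groups of 57/38/34 reviews, studies per review drawn as
#' 1 + negative binomial tuned to median 3 with IQR 1-35, grey-study
#' prevalences of 4.4% (non-English), 1.9% (unpublished) and 1.9%
#' (dissertations), search coverage of roughly 99%/96%/22% of reviews,
#' and a mix of dichotomous (risk-ratio) and continuous
#' (mean-difference) outcomes.
#'
#' @param n_reviews_per_group Named integer vector of reviews per group.
#' @param studies_per_review List `(size, mu)` for the negative-binomial
#'   part of `1 + rnbinom(size, mu)`.
#' @param label_prevalence Named probabilities that a study carries each
#'   grey-literature label (independent Bernoulli draws per label).
#' @param searched_probability Named probabilities that a review's
#'   search covers each study type.
#' @param prop_dichotomous Probability a review's outcome is
#'   dichotomous (pooled as RR) rather than continuous (MD).
#' @param true_effect List with `log_rr_mean`, `log_rr_sd` (dichotomous
#'   reviews, analysis scale) and `md_mean`, `md_sd` (continuous
#'   reviews, units of the outcome SD).
#' @param between_study_sd Between-study SD of true effects within a
#'   review, on the analysis scale; 0 gives a homogeneous corpus.
#' @param grey_effect_shift Additive shift on the analysis scale applied
#'   to studies carrying at least one grey label — the single explicit
#'   bias knob for simulation studies of language/publication bias.
#' @param baseline_risk Control-arm event risk for dichotomous studies.
#' @param arm_size List `(meanlog, sdlog, min)` for the log-normal
#'   per-arm sample-size draw (both arms equal).
#' @param model,method Pooling model and method recorded on every
#'   generated review.
#' @param year_range Publication-year range; years are sampled with
#'   linearly increasing weight so recent years dominate.
#' @param seed Optional integer seed; [generate_corpus()] is
#'   reproducible given the same seed.
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(
    n_reviews_per_group = c(ARI = 57, ID = 38, DPLP = 34),
    studies_per_review = list(size = 0.15, mu = 50),
    label_prevalence = c(non_english = 0.044, unpublished = 0.019,
                         dissertation = 0.019),
    searched_probability = c(non_english = 0.99, unpublished = 0.96,
                             dissertation = 0.22),
    prop_dichotomous = 0.6,
    true_effect = list(log_rr_mean = log(0.7), log_rr_sd = 0.15,
                       md_mean = -0.5, md_sd = 0.2),
    between_study_sd = 0.15,
    grey_effect_shift = 0,
    baseline_risk = 0.2,
    arm_size = list(meanlog = log(50), sdlog = 1.3, min = 10),
    model = "random",
    method = "inverse_variance",
    year_range = c(1990, 2013),
    seed = NULL) {
  if (is.null(names(n_reviews_per_group)) ||
      !all(names(n_reviews_per_group) %in% GROUPS))
    stop_input("'n_reviews_per_group' must be named with groups among %s",
               paste(GROUPS, collapse = ", "))
  for (i in seq_along(n_reviews_per_group))
    check_count(n_reviews_per_group[[i]], "n_reviews_per_group")
  if (!is.list(studies_per_review) ||
      !all(c("size", "mu") %in% names(studies_per_review)) ||
      studies_per_review$size <= 0 || studies_per_review$mu < 0)
    stop_input("'studies_per_review' must be list(size > 0, mu >= 0)")
  label_prevalence <- as.list(label_prevalence)
  searched_probability <- as.list(searched_probability)
  for (nm in LABELS) {
    check_prob(label_prevalence[[nm]] %||%
                 stop_input("'label_prevalence' is missing '%s'", nm),
               paste0("label_prevalence$", nm))
    check_prob(searched_probability[[nm]] %||%
                 stop_input("'searched_probability' is missing '%s'", nm),
               paste0("searched_probability$", nm))
  }
  label_prevalence <- unlist(label_prevalence[LABELS])
  searched_probability <- unlist(searched_probability[LABELS])
  check_prob(prop_dichotomous, "prop_dichotomous")
  for (nm in c("log_rr_mean", "log_rr_sd", "md_mean", "md_sd"))
    check_number(true_effect[[nm]] %||%
                   stop_input("'true_effect' is missing '%s'", nm),
                 paste0("true_effect$", nm))
  if (check_number(between_study_sd, "between_study_sd") < 0)
    stop_input("'between_study_sd' must be >= 0")
  check_number(grey_effect_shift, "grey_effect_shift")
  p <- check_prob(baseline_risk, "baseline_risk")
  if (p <= 0 || p >= 1) stop_input("'baseline_risk' must be in (0, 1)")
  if (!is.list(arm_size) || !all(c("meanlog", "sdlog", "min") %in% names(arm_size)))
    stop_input("'arm_size' must be list(meanlog, sdlog, min)")
  check_count(arm_size$min, "arm_size$min", min = 2)
  if (!(model %in% MODELS)) stop_input("unknown model '%s'", model)
  if (!(method %in% METHODS)) stop_input("unknown method '%s'", method)
  if (length(year_range) != 2 || year_range[1] > year_range[2])
    stop_input("'year_range' must be c(first, last)")
  if (!is.null(seed)) check_count(seed, "seed")
  structure(list(n_reviews_per_group = n_reviews_per_group,
                 studies_per_review = studies_per_review,
                 label_prevalence = label_prevalence,
                 searched_probability = searched_probability,
                 prop_dichotomous = prop_dichotomous,
                 true_effect = true_effect,
                 between_study_sd = between_study_sd,
                 grey_effect_shift = grey_effect_shift,
                 baseline_risk = baseline_risk,
                 arm_size = arm_size, model = model, method = method,
                 year_range = year_range, seed = seed),
            class = "generator_config")
}

draw_arm_size <- function(config) {
  max(config$arm_size$min,
      round(stats::rlnorm(1, config$arm_size$meanlog, config$arm_size$sdlog)))
}

#' Generate a synthetic review corpus
#'
#' Each review draws a true effect on its analysis scale; each study
#' draws a study-level effect (true effect + between-study noise +
#' `grey_effect_shift` if the study carries any grey label), then
#' arm-level data consistent with that effect: binomial event counts
#' from the effect-implied risks for dichotomous outcomes, or sample
#' means and SDs from their sampling distributions for continuous
#' outcomes. Labels and searched flags are independent Bernoulli draws
#' at the configured rates. Non-English studies are assigned a language
#' at frequencies typical of European-language trial reports.
#'
#' @param config A [generator_config()].
#' @return A list of [review_record()] objects; reproducible for a
#'   given `config$seed`.
#' @export
generate_corpus <- function(config = generator_config()) {
  if (!inherits(config, "generator_config"))
    stop_input("'config' must be created with generator_config()")
  if (!is.null(config$seed)) set.seed(config$seed)
  years <- seq(config$year_range[1], config$year_range[2])
  corpus <- list()
  for (g in names(config$n_reviews_per_group)) {
    for (i in seq_len(config$n_reviews_per_group[[g]])) {
      review_id <- sprintf("%s-%03d", g, i)
      k <- 1 + stats::rnbinom(1, size = config$studies_per_review$size,
                              mu = config$studies_per_review$mu)
      dich <- stats::runif(1) < config$prop_dichotomous
      theta <- if (dich)
        stats::rnorm(1, config$true_effect$log_rr_mean, config$true_effect$log_rr_sd)
      else
        stats::rnorm(1, config$true_effect$md_mean, config$true_effect$md_sd)
      searched <- vapply(LABELS, function(l)
        stats::runif(1) < config$searched_probability[[l]], logical(1))
      # grey studies only turn up in reviews whose search covered the
      # type (keeps included <= searched); within-searched prevalence is
      # rescaled so the corpus-wide marginal matches the configured rate
      prev <- vapply(LABELS, function(l) {
        if (!searched[[l]]) return(0)
        min(1, config$label_prevalence[[l]] / config$searched_probability[[l]])
      }, numeric(1))
      studies <- vector("list", k)
      for (j in seq_len(k)) {
        labels <- LABELS[stats::runif(3) < prev]
        delta <- theta + stats::rnorm(1, 0, config$between_study_sd) +
          if (length(labels)) config$grey_effect_shift else 0
        n <- draw_arm_size(config)
        language <- if ("non_english" %in% labels)
          sample(names(NONENGLISH_LANGUAGES), 1, prob = NONENGLISH_LANGUAGES)
        else NA_character_
        if (dich) {
          p_c <- config$baseline_risk
          p_t <- min(max(p_c * exp(delta), 1e-4), 0.99)
          outcome <- outcome_dichotomous(stats::rbinom(1, n, p_t), n,
                                         stats::rbinom(1, n, p_c), n)
        } else {
          outcome <- outcome_continuous(
            mean_t = stats::rnorm(1, delta, 1 / sqrt(n)),
            sd_t = sqrt(stats::rchisq(1, n - 1) / (n - 1)), n_t = n,
            mean_c = stats::rnorm(1, 0, 1 / sqrt(n)),
            sd_c = sqrt(stats::rchisq(1, n - 1) / (n - 1)), n_c = n)
        }
        studies[[j]] <- study_record(sprintf("%s-S%03d", review_id, j),
                                     outcome, labels = labels,
                                     language = language)
      }
      corpus[[length(corpus) + 1]] <- review_record(
        review_id, g, measure = if (dich) "RR" else "MD", studies = studies,
        model = config$model,
        method = if (dich) config$method else "inverse_variance",
        searched = stats::setNames(searched, LABELS),
        year = sample(years, 1, prob = seq_along(years)))
    }
  }
  corpus
}

#' Deterministic corpus matching a table of searching/inclusion counts
#'
#' Builds a minimal corpus whose [summarize_corpus()] output reproduces
#' a requested table of counts exactly: reviews per group, reviews
#' searching for and including each study type, total included studies
#' and included studies of each type. Used to reproduce published
#' corpus-level percentages without study-level data.
#'
#' @param counts Data frame with columns `group`, `label`, `n_reviews`,
#'   `n_searched`, `n_included`, `n_studies`, `n_studies_type`; one row
#'   per group x label. `n_reviews` and `n_studies` must agree across
#'   the labels of a group.
#' @return A list of [review_record()] objects.
#' @seealso [grey_search_counts()] for the published counts this
#'   reproduces.
#' @export
fixture_from_counts <- function(counts) {
  needed <- c("group", "label", "n_reviews", "n_searched", "n_included",
              "n_studies", "n_studies_type")
  if (!is.data.frame(counts) || !all(needed %in% names(counts)))
    stop_input("'counts' must be a data frame with columns %s",
               paste(needed, collapse = ", "))
  bad <- setdiff(unique(counts$label), LABELS)
  if (length(bad)) stop_input("unknown label(s): %s", paste(bad, collapse = ", "))
  corpus <- list()
  for (g in intersect(GROUPS, unique(counts$group))) {
    cg <- counts[counts$group == g, , drop = FALSE]
    n_reviews <- unique(cg$n_reviews)
    n_studies <- unique(cg$n_studies)
    if (length(n_reviews) != 1 || length(n_studies) != 1)
      stop_input("group '%s': n_reviews and n_studies must agree across labels", g)
    if (n_studies < n_reviews)
      stop_input("group '%s': fewer studies (%d) than reviews (%d)",
                 g, n_studies, n_reviews)
    for (i in seq_len(nrow(cg))) {
      r <- cg[i, ]
      if (r$n_included > r$n_searched || r$n_searched > n_reviews)
        stop_input("group '%s', label '%s': need included <= searched <= reviews",
                   g, r$label)
      if (r$n_included > r$n_studies_type)
        stop_input("group '%s', label '%s': %d including reviews need >= %d typed studies",
                   g, r$label, r$n_included, r$n_included)
      if (r$n_included == 0 && r$n_studies_type > 0)
        stop_input("group '%s', label '%s': typed studies but no including review",
                   g, r$label)
    }
    # typed studies: the first n_included reviews get one each, overflow
    # goes to the first review; untyped padding tops every review up to
    # >= 1 study and the group total up to n_studies
    study_labels <- rep(list(character()), n_reviews) # per review: label per typed study
    for (i in seq_len(nrow(cg))) {
      r <- cg[i, ]
      if (r$n_studies_type == 0) next
      alloc <- rep(0L, n_reviews)
      alloc[seq_len(r$n_included)] <- 1L
      alloc[1] <- alloc[1] + (r$n_studies_type - r$n_included)
      for (j in seq_len(n_reviews))
        study_labels[[j]] <- c(study_labels[[j]], rep(r$label, alloc[j]))
    }
    assigned <- vapply(study_labels, length, integer(1))
    pad <- pmax(0L, 1L - assigned)
    spare <- n_studies - sum(assigned) - sum(pad)
    if (spare < 0)
      stop_input("group '%s': %d studies cannot hold the typed allocation", g,
                 n_studies)
    pad[n_reviews] <- pad[n_reviews] + spare
    for (j in seq_len(n_reviews)) {
      labels_j <- c(as.list(study_labels[[j]]),
                    rep(list(character()), pad[j]))
      studies <- lapply(seq_along(labels_j), function(s)
        study_record(sprintf("%s-%03d-S%03d", g, j, s),
                     outcome_dichotomous(5, 10, 5, 10),
                     labels = labels_j[[s]]))
      searched <- vapply(LABELS, function(l) {
        row <- cg[cg$label == l, , drop = FALSE]
        nrow(row) == 1 && j <= row$n_searched
      }, logical(1))
      corpus[[length(corpus) + 1]] <- review_record(
        sprintf("%s-%03d", g, j), g, "RR", studies,
        model = "fixed", method = "inverse_variance",
        searched = stats::setNames(searched, LABELS), year = 2007)
    }
  }
  corpus
}
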