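REVIEW_COLS <- c("review_id", "group", "measure", "model", "method",
                 "searched_non_english", "searched_unpublished",
                 "searched_dissertations", "year")
STUDY_COLS <- c("review_id", "study_id", "is_non_english", "is_unpublished",
                "is_dissertation", "n_participants", "outcome_kind",
                "events_t", "total_t", "events_c", "total_c",
                "mean_t", "sd_t", "n_t", "mean_c", "sd_c", "n_c",
                "effect", "variance", "language")

corpus_tables <- function(corpus) {
  stopifnot(is.list(corpus),
            all(vapply(corpus, inherits, logical(1), "review_record")))
  reviews <- do.call(rbind, lapply(corpus, function(r) data.frame(
    review_id = r$review_id, group = r$group, measure = r$measure$code,
    model = r$model, method = r$method,
    searched_non_english = unname(r$searched[["non_english"]]),
    searched_unpublished = unname(r$searched[["unpublished"]]),
    searched_dissertations = unname(r$searched[["dissertation"]]),
    year = r$year, stringsAsFactors = FALSE)))
  studies <- do.call(rbind, lapply(corpus, function(r) {
    do.call(rbind, lapply(r$studies, function(s) {
      o <- s$outcome
      g <- function(nm) if (is.null(o[[nm]])) NA_real_ else o[[nm]]
      data.frame(
        review_id = r$review_id, study_id = s$study_id,
        is_non_english = has_label(s, "non_english"),
        is_unpublished = has_label(s, "unpublished"),
        is_dissertation = has_label(s, "dissertation"),
        n_participants = s$n_participants, outcome_kind = o$kind,
        events_t = g("events_t"), total_t = g("total_t"),
        events_c = g("events_c"), total_c = g("total_c"),
        mean_t = g("mean_t"), sd_t = g("sd_t"), n_t = g("n_t"),
        mean_c = g("mean_c"), sd_c = g("sd_c"), n_c = g("n_c"),
        effect = g("effect"), variance = g("variance"),
        language = s$language %||% NA_character_, stringsAsFactors = FALSE)
    }))
  }))
  reviews <- reviews[order(reviews$review_id), REVIEW_COLS, drop = FALSE]
  studies <- studies[order(studies$review_id, studies$study_id), STUDY_COLS,
                     drop = FALSE]
  rownames(reviews) <- rownames(studies) <- NULL
  list(reviews = reviews, studies = studies)
}

# full-precision number formatting so written corpora round-trip exactly
fmt_cell <- function(x) {
  if (is.numeric(x)) ifelse(is.na(x), "", sprintf("%.17g", x))
  else if (is.logical(x)) ifelse(is.na(x), "", ifelse(x, "TRUE", "FALSE"))
  else ifelse(is.na(x), "", as.character(x))
}

write_table_csv <- function(df, path) {
  lines <- paste(names(df), collapse = ",")
  if (nrow(df) > 0) {
    cells <- vapply(df, fmt_cell, character(nrow(df)))
    if (nrow(df) == 1) cells <- matrix(cells, nrow = 1)
    lines <- c(lines, apply(cells, 1, paste, collapse = ","))
  }
  writeLines(lines, path, useBytes = TRUE)
}

#' Write a corpus to disk
#'
#' Writes `reviews.csv` and `studies.csv` (UTF-8, comma-separated,
#' header row, `.` decimal separator, full numeric precision) into a
#' directory, or a single nested JSON file when `path` ends in
#' `.json`. Output is deterministic: rows ordered by review then study
#' id, byte-identical across runs for identical corpora.
#'
#' @param corpus List of [review_record()] objects.
#' @param path Directory for the CSV pair, or a `*.json` file path.
#' @return `path`, invisibly.
#' @export
write_corpus <- function(corpus, path) {
  tabs <- corpus_tables(corpus)
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(tabs, path, dataframe = "rows", na = "null",
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  } else {
    if (!dir.exists(path)) dir.create(path, recursive = TRUE)
    write_table_csv(tabs$reviews, file.path(path, "reviews.csv"))
    write_table_csv(tabs$studies, file.path(path, "studies.csv"))
  }
  invisible(path)
}

schema_error <- function(file, row, column, msg) {
  stop_input("%s, row %s, column '%s': %s", file, row, column, msg)
}

#' Read a corpus from disk
#'
#' Reads the two-table corpus schema written by [write_corpus()] (a
#' directory holding `reviews.csv` and `studies.csv`, or a single
#' `.json` file) and validates it: enum fields, outcome payloads
#' determined by `outcome_kind`, referential integrity between studies
#' and reviews, and at least one study per review. Violations are
#' reported with file, row and column.
#'
#' @param path Directory or `.json` file written by [write_corpus()].
#' @return A list of [review_record()] objects.
#' @export
read_corpus <- function(path) {
  if (grepl("\\.json$", path)) {
    if (!file.exists(path)) stop_input("no such file: %s", path)
    tabs <- jsonlite::fromJSON(path)
    reviews <- as.data.frame(tabs$reviews, stringsAsFactors = FALSE)
    studies <- as.data.frame(tabs$studies, stringsAsFactors = FALSE)
    rev_file <- stu_file <- path
  } else {
    rev_file <- file.path(path, "reviews.csv")
    stu_file <- file.path(path, "studies.csv")
    if (!file.exists(rev_file) || !file.exists(stu_file))
      stop_input("corpus directory '%s' must contain reviews.csv and studies.csv",
                 path)
    reviews <- utils::read.csv(rev_file, stringsAsFactors = FALSE,
                               colClasses = c(review_id = "character"))
    studies <- utils::read.csv(stu_file, stringsAsFactors = FALSE,
                               colClasses = c(review_id = "character",
                                              study_id = "character"))
  }
  for (col in REVIEW_COLS)
    if (!col %in% names(reviews))
      stop_input("%s: missing column '%s'", rev_file, col)
  for (col in STUDY_COLS)
    if (!col %in% names(studies))
      stop_input("%s: missing column '%s'", stu_file, col)
  if (anyDuplicated(reviews$review_id))
    stop_input("%s: duplicated review_id", rev_file)
  orphans <- !(studies$review_id %in% reviews$review_id)
  if (any(orphans))
    schema_error(stu_file, which(orphans)[1], "review_id",
                 sprintf("study '%s' references unknown review '%s'",
                         studies$study_id[which(orphans)[1]],
                         studies$review_id[which(orphans)[1]]))
  corpus <- vector("list", nrow(reviews))
  for (i in seq_len(nrow(reviews))) {
    rv <- reviews[i, ]
    if (!(rv$measure %in% MEASURES))
      schema_error(rev_file, i, "measure",
                   sprintf("unknown summary measure '%s'", rv$measure))
    if (!(rv$group %in% GROUPS))
      schema_error(rev_file, i, "group", sprintf("unknown group '%s'", rv$group))
    if (!(rv$model %in% MODELS))
      schema_error(rev_file, i, "model", sprintf("unknown model '%s'", rv$model))
    if (!(rv$method %in% METHODS))
      schema_error(rev_file, i, "method", sprintf("unknown method '%s'", rv$method))
    for (col in c("searched_non_english", "searched_unpublished",
                  "searched_dissertations"))
      if (is.na(rv[[col]]) || !is.logical(rv[[col]]))
        schema_error(rev_file, i, col, "must be TRUE or FALSE")
    rows <- which(studies$review_id == rv$review_id)
    if (length(rows) == 0)
      schema_error(rev_file, i, "review_id",
                   sprintf("review '%s' has no studies", rv$review_id))
    studs <- lapply(rows, function(j) {
      st <- studies[j, ]
      need <- function(cols) {
        for (col in cols)
          if (is.na(st[[col]]))
            schema_error(stu_file, j, col,
                         sprintf("required for outcome_kind '%s'", st$outcome_kind))
      }
      outcome <- switch(
        as.character(st$outcome_kind),
        dichotomous = { need(c("events_t", "total_t", "events_c", "total_c"))
          outcome_dichotomous(st$events_t, st$total_t, st$events_c, st$total_c) },
        continuous = { need(c("mean_t", "sd_t", "n_t", "mean_c", "sd_c", "n_c"))
          outcome_continuous(st$mean_t, st$sd_t, st$n_t, st$mean_c, st$sd_c, st$n_c) },
        effect = { need(c("effect", "variance"))
          outcome_effect(st$effect, st$variance) },
        schema_error(stu_file, j, "outcome_kind",
                     sprintf("unknown outcome_kind '%s'", st$outcome_kind)))
      for (col in c("is_non_english", "is_unpublished", "is_dissertation"))
        if (is.na(st[[col]]) || !is.logical(st[[col]]))
          schema_error(stu_file, j, col, "must be TRUE or FALSE")
      labels <- LABELS[c(st$is_non_english, st$is_unpublished, st$is_dissertation)]
      study_record(st$study_id, outcome, labels = labels,
                   n_participants = if (is.na(st$n_participants)) NULL
                                    else st$n_participants,
                   language = if (is.na(st$language) || identical(st$language, ""))
                     NA_character_ else st$language)
    })
    corpus[[i]] <- review_record(
      rv$review_id, rv$group, rv$measure, studs, model = rv$model,
      method = rv$method,
      searched = c(non_english = rv$searched_non_english,
                   unpublished = rv$searched_unpublished,
                   dissertation = rv$searched_dissertations),
      year = if (is.na(rv$year)) NA_integer_ else rv$year)
  }
  corpus
}

md_table <- function(df) {
  header <- c(paste0("| ", paste(names(df), collapse = " | "), " |"),
              paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|"))
  if (nrow(df) == 0) return(header)
  cells <- vapply(df, function(x) ifelse(is.na(x), "NA", as.character(x)),
                  character(nrow(df)))
  if (nrow(df) == 1) cells <- matrix(cells, nrow = 1)
  c(header,
    apply(cells, 1, function(r) paste0("| ", paste(r, collapse = " | "), " |")))
}

#' Write corpus-summary and impact reports
#'
#' Writes `corpus_summary.csv`/`.md` and `impact_report.csv`/`.md` into
#' `outdir`. Pooled estimates are formatted to two decimals,
#' percentages to one decimal (half away from zero), non-estimable
#' cells render as `NA`; rows are ordered by label then review id, so
#' output bytes are deterministic for identical inputs.
#'
#' @param summary A [summarize_corpus()] result (or `NULL` to skip).
#' @param impacts A [run_corpus_impacts()] data frame (or `NULL`).
#' @param outdir Output directory, created if needed.
#' @return Character vector of files written, invisibly.
#' @export
write_reports <- function(summary, impacts, outdir) {
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  written <- character()
  if (!is.null(summary)) {
    s <- as.data.frame(summary)
    for (col in grep("^pct_", names(s), value = TRUE))
      s[[col]] <- fmt_num(s[[col]], 1)
    f <- file.path(outdir, "corpus_summary.csv")
    write_table_csv(s, f)
    writeLines(md_table(s), file.path(outdir, "corpus_summary.md"),
               useBytes = TRUE)
    written <- c(written, f, file.path(outdir, "corpus_summary.md"))
  }
  if (!is.null(impacts)) {
    im <- impacts[order(match(impacts$label, LABELS), impacts$review_id), ,
                  drop = FALSE]
    for (col in grep("^pct_", names(im), value = TRUE))
      im[[col]] <- fmt_num(im[[col]], 1)
    im$point_with <- fmt_num(im$point_with, 2)
    im$point_without <- fmt_num(im$point_without, 2)
    f <- file.path(outdir, "impact_report.csv")
    write_table_csv(im, f)
    writeLines(md_table(im), file.path(outdir, "impact_report.md"),
               useBytes = TRUE)
    written <- c(written, f, file.path(outdir, "impact_report.md"))
  }
  invisible(written)
}
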