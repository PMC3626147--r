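# File formats: the survey CSV dialect, dataset export, JSON reports.

survey_item_cols <- function() paste0("item_", 1:22)

#' Read a survey response file
#'
#' Comma-separated, UTF-8, header required. One row per participant per
#' timepoint with columns `participant_id`, `timepoint` ("pre"/"post"),
#' `stage` (integer code 1-5, see [stage_from_code()]) and `item_1` ...
#' `item_22` (Likert 1-5, instrument listing order). Malformed values are
#' reported with their row number.
#'
#' @param path Path to the CSV file.
#' @return Data frame of typed survey records.
#' @export
read_survey <- function(path) {
  if (!file.exists(path)) stop("survey file not found: ", path,
                               call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character", fileEncoding = "UTF-8")
  required <- c("participant_id", "timepoint", "stage", survey_item_cols())
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("survey header is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  bad_tp <- which(!df$timepoint %in% c("pre", "post"))
  if (length(bad_tp)) {
    stop("invalid timepoint in row(s) ", paste(bad_tp, collapse = ", "),
         " (expected 'pre' or 'post')", call. = FALSE)
  }
  to_int <- function(col, lo, hi, what) {
    v <- suppressWarnings(as.integer(df[[col]]))
    bad <- which(is.na(v) | v < lo | v > hi | v != as.numeric(df[[col]]))
    if (length(bad)) {
      stop(sprintf("invalid %s value '%s' in column %s, row %d",
                   what, df[[col]][bad[1]], col, bad[1]), call. = FALSE)
    }
    v
  }
  df$stage <- to_int("stage", 1, 5, "stage code")
  for (col in survey_item_cols()) {
    df[[col]] <- to_int(col, 1, 5, "Likert")
  }
  dup <- duplicated(df[c("participant_id", "timepoint")])
  if (any(dup)) {
    stop("duplicate participant/timepoint in row(s) ",
         paste(which(dup), collapse = ", "), call. = FALSE)
  }
  df
}

#' Write a survey response file
#'
#' Inverse of [read_survey()]; a write-then-read round trip is the identity.
#'
#' @param survey Survey data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_survey <- function(survey, path) {
  utils::write.csv(survey, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Write a simulated trial dataset to files
#'
#' Writes `survey.csv` (the item-level responses in the [read_survey()]
#' format) and `outcomes.csv` (per-participant arm, demographics, stages and
#' FOBT outcome) into a directory.
#'
#' @param dataset A `trial_dataset` (with item responses, i.e. simulated with
#'   all scales).
#' @param dir Output directory (created if needed).
#' @return Named character vector of the two file paths, invisibly.
#' @export
write_trial_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "trial_dataset"))
  if (is.null(dataset$responses)) {
    stop("dataset has no item-level responses (simulate all scales)",
         call. = FALSE)
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  survey_path <- file.path(dir, "survey.csv")
  outcomes_path <- file.path(dir, "outcomes.csv")
  write_survey(dataset$responses, survey_path)
  utils::write.csv(dataset$participants, outcomes_path, row.names = FALSE,
                   quote = FALSE, fileEncoding = "UTF-8")
  invisible(c(survey = survey_path, outcomes = outcomes_path))
}

# Recursively convert result objects to plain lists for JSON.
report_to_list <- function(x) {
  if (inherits(x, "chisq_result")) {
    list(statistic = x$statistic, df = x$df, p = x$p,
         corrected = x$corrected)
  } else if (inherits(x, "anova_table")) {
    stats::setNames(lapply(seq_len(nrow(x)), function(i) {
      list(F = x$F[i], df = c(x$df1[i], x$df2[i]), p = x$p[i])
    }), x$term)
  } else if (is.list(x) && !is.data.frame(x)) {
    lapply(x, report_to_list)
  } else {
    x
  }
}

#' Serialize an analysis report to JSON
#'
#' @param report An `analysis_report` (or any nested list of results).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(report_to_list(unclass(report)), path,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
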