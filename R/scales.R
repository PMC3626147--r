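# Measurement scales: PHM constructs, self-efficacy, fecal aversion.

the <- new.env(parent = emptyenv())

#' Names of the seven measurement scales
#'
#' Five Preventive Health Model constructs plus self-efficacy and fecal
#' aversion, in instrument listing order.
#'
#' @return Character vector of length 7.
#' @export
scale_factors <- function() {
  c("salience_coherence", "social_influence", "cancer_worries",
    "perceived_susceptibility", "response_efficacy", "self_efficacy",
    "fecal_aversion")
}

#' The six factors with tailored message variants
#'
#' All scales except cancer worries (concern is addressed through the other
#' factors' messages, so no worries variant exists in a message library).
#'
#' @return Character vector of length 6.
#' @export
tailorable_factors <- function() {
  setdiff(scale_factors(), "cancer_worries")
}

#' Scale registry
#'
#' Definitions of the seven Likert scales: item ids and wording, reverse-coding
#' flags, the designated tailoring item (the single statement whose raw 1-5
#' response keys message selection; absent for cancer worries) and the
#' internal consistency (Cronbach's alpha) reported for the instrument.
#'
#' @return A named list of `scale_definition` objects, one per factor. Each has
#'   elements `factor`, `items` (character vector of item ids), `item_text`,
#'   `reverse_coded` (subset of `items`), `tailoring_item` (item id or `NA`),
#'   and `reported_alpha`.
#' @examples
#' phm_scales()$fecal_aversion
#' @export
phm_scales <- function() {
  if (!is.null(the$scales)) {
    return(the$scales)
  }
  path <- system.file("extdata", "phm_scales.json", package = "crctailor",
                      mustWork = TRUE)
  raw <- jsonlite::read_json(path)
  scales <- lapply(raw$scales, function(s) {
    items <- vapply(s$items, `[[`, "", "item_id")
    def <- list(
      factor = s$factor,
      items = items,
      item_text = stats::setNames(vapply(s$items, `[[`, "", "text"), items),
      reverse_coded = items[vapply(s$items, `[[`, FALSE, "reverse_coded")],
      tailoring_item = {
        t <- items[vapply(s$items, `[[`, FALSE, "tailoring")]
        if (length(t)) t[[1]] else NA_character_
      },
      reported_alpha = s$reported_alpha
    )
    class(def) <- "scale_definition"
    def
  })
  names(scales) <- vapply(scales, `[[`, "", "factor")
  stopifnot(identical(names(scales), scale_factors()))
  the$scales <- scales
  scales
}

#' @export
print.scale_definition <- function(x, ...) {
  cat(sprintf("<scale '%s': %d items, %d reverse coded, alpha %.2f>\n",
              x$factor, length(x$items), length(x$reverse_coded),
              x$reported_alpha))
  invisible(x)
}

check_likert <- function(values, what = "response") {
  bad <- !is.finite(values) | values != as.integer(values) |
    values < 1 | values > 5
  if (any(bad)) {
    stop(sprintf("%s values must be integers in 1..5; offending: %s",
                 what, paste(values[bad], collapse = ", ")), call. = FALSE)
  }
  invisible(as.integer(values))
}

#' Score one scale for one respondent
#'
#' Sum scoring of 1-5 Likert responses with reverse-coded items mapped through
#' `6 - v`. Scores therefore range from the item count (all most
#' screening-inconsistent) to five times the item count.
#'
#' @param responses Named integer vector of Likert values in 1..5; names are
#'   item ids and must cover every item of `scale` (extra items are ignored).
#' @param scale A `scale_definition` from [phm_scales()].
#' @return A `scale_score` list: `factor`, `value`, `min_possible`,
#'   `max_possible`.
#' @examples
#' sc <- phm_scales()$fecal_aversion
#' score_scale(c(fa_1 = 1, fa_2 = 1, fa_3 = 1), sc)$value # 15: all reversed
#' @export
score_scale <- function(responses, scale) {
  stopifnot(inherits(scale, "scale_definition"))
  if (is.null(names(responses))) {
    stop("responses must be named by item id", call. = FALSE)
  }
  missing <- setdiff(scale$items, names(responses))
  if (length(missing)) {
    stop(sprintf("missing response(s) for item(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  v <- check_likert(responses[scale$items])
  rev <- scale$items %in% scale$reverse_coded
  value <- sum(ifelse(rev, 6L - v, v))
  k <- length(scale$items)
  structure(list(factor = scale$factor, value = as.integer(value),
                 min_possible = k, max_possible = 5L * k),
            class = "scale_score")
}

#' @export
print.scale_score <- function(x, ...) {
  cat(sprintf("<%s score: %d (range %d-%d)>\n", x$factor, x$value,
              x$min_possible, x$max_possible))
  invisible(x)
}

#' Score all seven scales for a survey table
#'
#' @param survey A survey data frame as returned by [read_survey()]:
#'   columns `participant_id`, `timepoint`, `stage`, `item_1` ... `item_22`,
#'   where items follow the registry listing order (see [phm_scales()]).
#' @return A data frame with `participant_id`, `timepoint`, `stage` and one
#'   integer score column per factor.
#' @export
score_survey <- function(survey) {
  scales <- phm_scales()
  item_ids <- unlist(lapply(scales, `[[`, "items"), use.names = FALSE)
  item_cols <- paste0("item_", seq_along(item_ids))
  missing <- setdiff(item_cols, names(survey))
  if (length(missing)) {
    stop("survey is missing item columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  out <- survey[, intersect(c("participant_id", "timepoint", "stage"),
                            names(survey)), drop = FALSE]
  mat <- as.matrix(survey[, item_cols])
  colnames(mat) <- item_ids
  for (sc in scales) {
    out[[sc$factor]] <- vapply(seq_len(nrow(mat)), function(i) {
      score_scale(mat[i, ], sc)$value
    }, integer(1))
  }
  out
}

#' Cronbach's alpha
#'
#' Internal consistency of a set of items:
#' `alpha = k/(k-1) * (1 - sum(item variances) / variance of item sums)`.
#' Reverse-coded items must already be recoded before calling.
#'
#' @param item_matrix Numeric matrix or data frame, participants in rows,
#'   items in columns. At least 2 items and 3 participants.
#' @return Numeric scalar.
#' @examples
#' x <- matrix(sample(1:5, 40, TRUE), ncol = 2)
#' cronbach_alpha(cbind(x, x)) # duplicated block raises alpha
#' @export
cronbach_alpha <- function(item_matrix) {
  m <- as.matrix(item_matrix)
  if (ncol(m) < 2) stop("need at least 2 items", call. = FALSE)
  if (nrow(m) < 3) stop("need at least 3 participants", call. = FALSE)
  if (anyNA(m)) stop("item matrix contains missing values", call. = FALSE)
  total_var <- stats::var(rowSums(m))
  if (total_var <= 0) {
    stop("total score variance is zero; alpha is undefined", call. = FALSE)
  }
  k <- ncol(m)
  k / (k - 1) * (1 - sum(apply(m, 2, stats::var)) / total_var)
}

#' PAPM decision stages
#'
#' The five Precaution Adoption Process Model stages for FOBT screening, in
#' ordinal order from least to most ready to act.
#'
#' @return Character vector of length 5.
#' @export
papm_stages <- function() {
  c("never_heard", "not_considered", "decided_against", "undecided",
    "decided_to_act")
}

#' Decode a 1-5 stage code to a PAPM stage
#'
#' Survey files carry the decision stage as an integer code 1-5 mapping onto
#' [papm_stages()] in listed order (1 = never heard of FOBT, 5 = decided to
#' use FOBT).
#'
#' @param code Integer vector with values in 1..5.
#' @return Factor with levels [papm_stages()].
#' @export
stage_from_code <- function(code) {
  if (any(!is.finite(code) | code != as.integer(code) | code < 1 | code > 5)) {
    stop("stage codes must be integers in 1..5", call. = FALSE)
  }
  factor(papm_stages()[as.integer(code)], levels = papm_stages())
}
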