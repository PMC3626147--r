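# Trial design: arm allocation, FOBT outcome classification, decision-stage
# movement, participant-flow accounting, and the exploratory study's printed
# tables as reusable inputs.

#' Study arms
#'
#' The five conditions of the 2 x 2 x 2 factorial design (modality x message,
#' plus an untreated control).
#'
#' @return Character vector of length 5.
#' @export
study_arms <- function() {
  c("control", "paper_nontailored", "paper_tailored", "web_nontailored",
    "web_tailored")
}

#' Modality and message type of an arm
#'
#' @param arm Character vector of arm names from [study_arms()].
#' @return `arm_modality()`: "paper", "web" or "none"; `arm_message()`:
#'   "tailored", "nontailored" or "none".
#' @export
arm_modality <- function(arm) {
  stopifnot(all(arm %in% study_arms()))
  ifelse(arm == "control", "none",
         ifelse(startsWith(arm, "web"), "web", "paper"))
}

#' @rdname arm_modality
#' @export
arm_message <- function(arm) {
  stopifnot(all(arm %in% study_arms()))
  ifelse(arm == "control", "none",
         ifelse(endsWith(arm, "_tailored"), "tailored", "nontailored"))
}

#' Randomly allocate participants to arms
#'
#' Uniform random assignment balanced to within one participant across arms.
#' Ids are sorted before assignment, so the result depends only on the id set
#' and the seed, not on input order.
#'
#' @param participant_ids Vector of unique ids.
#' @param arms Character vector of arm names (default [study_arms()]).
#' @param seed Integer seed; identical inputs and seed give identical output.
#' @return Named character vector: arm per participant id.
#' @export
allocate <- function(participant_ids, arms = study_arms(), seed) {
  if (!length(participant_ids)) stop("no participants to allocate",
                                     call. = FALSE)
  if (!length(arms)) stop("no arms to allocate to", call. = FALSE)
  if (anyDuplicated(participant_ids)) {
    stop("participant ids must be unique", call. = FALSE)
  }
  ids <- sort(as.character(participant_ids))
  n <- length(ids)
  k <- length(arms)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  sizes <- rep(n %/% k, k)
  extra <- n %% k
  if (extra > 0) {
    lucky <- sample.int(k, extra)
    sizes[lucky] <- sizes[lucky] + 1L
  }
  assignment <- sample(rep(arms, sizes))
  stats::setNames(assignment, ids)
}

#' Classify an FOBT outcome at the 6/12-week cut-offs
#'
#' Kits returned within 6 weeks of dispatch are "early", within 6-12 weeks
#' "late" (both cut-offs inclusive); a requested kit not returned by week 12
#' counts as not screened ("non_return").
#'
#' @param requested Logical: was a kit requested?
#' @param return_week Weeks from dispatch to receipt, or `NA` if not returned.
#' @param request_channel "at_interview", "after_interview" or "none".
#' @return An `fobt_outcome` list: `requested`, `request_channel`,
#'   `return_week`, `status` (one of "early", "late", "non_return",
#'   "not_requested").
#' @examples
#' classify_fobt(TRUE, 6)$status   # "early" (boundary inclusive)
#' classify_fobt(TRUE, 13)$status  # "non_return"
#' @export
classify_fobt <- function(requested, return_week = NA_real_,
                          request_channel = if (requested) "at_interview"
                          else "none") {
  stopifnot(is.logical(requested), length(requested) == 1)
  if (!is.na(return_week) && !requested) {
    stop("a return week was recorded but no kit was requested",
         call. = FALSE)
  }
  if (!is.na(return_week) && return_week <= 0) {
    stop("return_week must be positive", call. = FALSE)
  }
  status <- if (!requested) {
    "not_requested"
  } else if (is.na(return_week) || return_week > 12) {
    "non_return"
  } else if (return_week <= 6) {
    "early"
  } else {
    "late"
  }
  structure(list(requested = requested, request_channel = request_channel,
                 return_week = if (status %in% c("early", "late"))
                   return_week else NA_real_,
                 status = status),
            class = "fobt_outcome")
}

#' Classify movement in PAPM decision stage
#'
#' Movement is dichotomized as "moved to screen" (post-intervention stage is
#' decided_to_act, pre was not) versus any other movement; participants who
#' had already decided to screen at both timepoints are excluded from the
#' movement analysis.
#'
#' @param pre,post PAPM stages (see [papm_stages()]).
#' @return One of "moved_to_screen", "other_movement", "excluded_predecided".
#' @export
classify_movement <- function(pre, post) {
  pre <- as.character(pre)
  post <- as.character(post)
  stopifnot(pre %in% papm_stages(), post %in% papm_stages())
  if (pre == "decided_to_act" && post == "decided_to_act") {
    "excluded_predecided"
  } else if (post == "decided_to_act") {
    "moved_to_screen"
  } else {
    "other_movement"
  }
}

# Round half away from zero, the convention matching the study's printed
# percentages (base round() is round-half-even).
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Participant-flow report with percentages
#'
#' Computes `count / denominator` percentages (half-up, one decimal) for each
#' stage of a recruitment funnel.
#'
#' @param stages Data frame with columns `stage` (label), `count` and
#'   `denominator`; use the same `denominator` for sibling branches. An
#'   optional logical column `inflow` flags external additions (e.g. snowball
#'   recruits) that are exempt from the count-within-parent check.
#' @return A `flow_funnel` data frame: input columns plus `percent`.
#' @examples
#' funnel_report(data.frame(stage = "analyzed", count = 104,
#'                          denominator = 119))
#' @export
funnel_report <- function(stages) {
  stopifnot(is.data.frame(stages),
            all(c("stage", "count", "denominator") %in% names(stages)))
  if (any(stages$count < 0)) stop("counts must be non-negative",
                                  call. = FALSE)
  if (any(stages$denominator <= 0)) stop("zero or negative denominator",
                                         call. = FALSE)
  inflow <- if ("inflow" %in% names(stages)) stages$inflow else
    rep(FALSE, nrow(stages))
  if (any(!inflow & stages$count > stages$denominator)) {
    stop("stage count exceeds its denominator (flag external inflow rows ",
         "with inflow = TRUE)", call. = FALSE)
  }
  stages$percent <- round_half_up(100 * stages$count / stages$denominator, 1)
  class(stages) <- c("flow_funnel", "data.frame")
  stages
}

#' Printed recruitment and outcome counts of the exploratory study
#'
#' The participant-flow counts of the exploratory CRC screening trial that
#' this package models, usable directly with [funnel_report()]: sampling
#' frame, contacts, declines, ineligibles, consents, snowball additions,
#' attendance and FOBT request/return counts.
#'
#' @return Data frame with columns `stage`, `count`, `denominator`, `inflow`.
#' @export
study_flow_counts <- function() {
  data.frame(
    stage = c("contacted", "declined", "ineligible", "agreed",
              "snowball_added", "attended", "requested_at_interview",
              "requested_total", "returned", "returned_early"),
    count = c(532, 298, 134, 100, 19, 104, 61, 70, 41, 27),
    denominator = c(756, 532, 532, 756, 100, 119, 104, 104, 70, 41),
    inflow = c(FALSE, FALSE, FALSE, FALSE, TRUE, FALSE, FALSE, FALSE,
               FALSE, FALSE),
    stringsAsFactors = FALSE
  )
}

#' Printed baseline-comparability tables of the exploratory study
#'
#' Demographic contingency tables (counts per arm) and the age summary
#' statistics of the analyzed sample (n = 104), for baseline group
#' comparability checks: chi-square for the categorical variables (see
#' [chi_square()]) and one-way ANOVA for age reconstructed from summary
#' statistics (see [groups_from_summary()]).
#'
#' @return List with element `tables` (named list of matrices, columns in arm
#'   order paper_nontailored, paper_tailored, web_nontailored, web_tailored,
#'   control) and `age` (data frame of per-arm `mean`, `sd`, `n`).
#' @export
baseline_tables <- function() {
  arms <- c("paper_nontailored", "paper_tailored", "web_nontailored",
            "web_tailored", "control")
  mk <- function(m, rows) {
    dimnames(m) <- list(rows, arms)
    m
  }
  list(
    tables = list(
      gender = mk(rbind(c(15, 10, 10, 8, 9),
                        c(7, 11, 10, 13, 11)), c("male", "female")),
      education = mk(rbind(c(6, 7, 4, 7, 10),
                           c(6, 6, 8, 7, 8),
                           c(10, 8, 8, 7, 2)),
                     c("some_high_school", "completed_high_school_trade",
                       "university")),
      birthplace = mk(rbind(c(18, 15, 13, 18, 19),
                            c(4, 6, 7, 3, 1)),
                      c("within_australia", "outside_australia")),
      relationship = mk(rbind(c(18, 15, 17, 15, 15),
                              c(4, 6, 3, 6, 5)), c("with_partner", "single")),
      heard_fobt = mk(rbind(c(11, 9, 10, 12, 13),
                            c(11, 12, 10, 9, 7)),
                      c("never_heard", "heard"))
    ),
    age = data.frame(
      arm = arms,
      mean = c(61, 62, 60, 59, 62),
      sd = c(7.0, 6.4, 6.2, 7.9, 6.8),
      n = c(22, 21, 20, 21, 20),
      stringsAsFactors = FALSE
    )
  )
}

#' Printed FOBT request/return tables of the exploratory study
#'
#' The four 2 x 2 tables behind the intervention-group FOBT comparisons:
#' requested and returned, each split by modality (web n = 41 vs paper
#' n = 43) and by message type (tailored n = 42 vs non-tailored n = 42).
#' Non-event counts use the full group sizes as denominators (for "returned",
#' the complement is the whole group, not just requesters).
#'
#' @return Named list of four 2 x 2 integer matrices (rows = groups,
#'   columns = event yes/no) ready for [chi_square()] with `yates = TRUE`.
#' @export
fobt_tables <- function() {
  mk <- function(events, sizes, rows) {
    m <- cbind(yes = events, no = sizes - events)
    rownames(m) <- rows
    m
  }
  list(
    requested_by_modality = mk(c(28, 34), c(41, 43), c("web", "paper")),
    requested_by_message = mk(c(34, 28), c(42, 42),
                              c("tailored", "nontailored")),
    returned_by_modality = mk(c(18, 18), c(41, 43), c("web", "paper")),
    returned_by_message = mk(c(22, 14), c(42, 42),
                             c("tailored", "nontailored"))
  )
}
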