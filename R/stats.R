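# Analysis battery: chi-square (optionally Yates-corrected), one-way ANOVA,
# related-samples t tests, and the 2 x 2 x 2 mixed between-within ANOVA.

#' Chi-square test on a contingency table
#'
#' Pearson chi-square of independence. With `yates = TRUE` on a 2 x 2 table,
#' the Yates continuity correction is applied: 0.5 is subtracted from each
#' |O - E| (never below zero). Requesting the correction on a larger table
#' falls back to the uncorrected statistic with a warning.
#'
#' @param table Matrix of non-negative counts, at least 2 x 2.
#' @param yates Apply the continuity correction (2 x 2 tables only)?
#' @return A `chisq_result` list: `statistic`, `df`, `p`, `corrected`.
#' @examples
#' chi_square(fobt_tables()$requested_by_modality, yates = TRUE)
#' @export
chi_square <- function(table, yates = FALSE) {
  m <- as.matrix(table)
  if (nrow(m) < 2 || ncol(m) < 2) {
    stop("need at least 2 rows and 2 columns", call. = FALSE)
  }
  if (any(m < 0) || any(m != round(m))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  expected <- outer(rowSums(m), colSums(m)) / sum(m)
  if (any(expected == 0)) {
    stop("zero expected count; chi-square is undefined", call. = FALSE)
  }
  is2x2 <- all(dim(m) == 2)
  if (yates && !is2x2) {
    warning("Yates correction applies to 2 x 2 tables only; ",
            "computing the uncorrected statistic")
  }
  corrected <- yates && is2x2
  res <- suppressWarnings(stats::chisq.test(m, correct = corrected))
  structure(list(statistic = unname(res$statistic),
                 df = unname(res$parameter),
                 p = res$p.value,
                 corrected = corrected),
            class = "chisq_result")
}

#' @export
print.chisq_result <- function(x, ...) {
  cat(sprintf("chi-square%s = %.4f, df = %d, p = %.4g\n",
              if (x$corrected) " (Yates)" else "", x$statistic, x$df, x$p))
  invisible(x)
}

#' One-way analysis of variance
#'
#' Classical between/within decomposition with equal variances assumed.
#'
#' @param groups List of numeric vectors, one per group (>= 2 groups, each
#'   with >= 2 observations).
#' @return List with `F`, `df` (numerator, denominator), `p`.
#' @export
one_way_anova <- function(groups) {
  if (!is.list(groups) || length(groups) < 2) {
    stop("need a list of at least 2 groups", call. = FALSE)
  }
  ns <- lengths(groups)
  if (any(ns < 2)) stop("every group needs at least 2 observations",
                        call. = FALSE)
  y <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), ns))
  ssw <- sum(vapply(groups, function(x) sum((x - mean(x))^2), numeric(1)))
  if (ssw <= 0) stop("zero within-group variance; F is undefined",
                     call. = FALSE)
  a <- stats::anova(stats::lm(y ~ g))
  list(F = a$`F value`[1], df = c(a$Df[1], a$Df[2]), p = a$`Pr(>F)`[1])
}

#' Reconstruct group samples from summary statistics
#'
#' Builds, for each group, a sample with exactly the given mean and standard
#' deviation (a standardized equispaced grid rescaled to the target moments).
#' Because one-way ANOVA depends on the data only through per-group means,
#' SDs and sizes, feeding these samples to [one_way_anova()] reproduces the F
#' statistic implied by published summary tables.
#'
#' @param means,sds,ns Numeric vectors of equal length (one entry per group);
#'   `ns >= 2`, `sds > 0`.
#' @return List of numeric vectors.
#' @examples
#' age <- baseline_tables()$age
#' one_way_anova(groups_from_summary(age$mean, age$sd, age$n))
#' @export
groups_from_summary <- function(means, sds, ns) {
  stopifnot(length(means) == length(sds), length(means) == length(ns),
            all(ns >= 2), all(sds > 0))
  Map(function(m, s, n) {
    z <- as.vector(scale(seq_len(n)))
    m + s * z
  }, means, sds, ns)
}

#' Related-samples (paired) t test
#'
#' @param pre,post Numeric vectors of equal length (n >= 2) for the same
#'   participants at two timepoints.
#' @return List with `t`, `df`, `p` (two-sided).
#' @export
paired_t <- function(pre, post) {
  if (length(pre) != length(post)) stop("pre and post differ in length",
                                        call. = FALSE)
  if (length(pre) < 2) stop("need at least 2 pairs", call. = FALSE)
  d <- post - pre
  if (stats::var(d) == 0) {
    stop("zero variance of differences; t is undefined", call. = FALSE)
  }
  res <- stats::t.test(post, pre, paired = TRUE)
  list(t = unname(res$statistic), df = unname(res$parameter),
       p = res$p.value)
}

# Type III 1-df F tests on a 2 x 2 cell layout: response y, sum-coded factors
# message (m) and modality (o). Returns F and p per contrast. Cell order:
# (m,o) = (-1,-1), (-1,+1), (+1,-1), (+1,+1).
type3_cell_tests <- function(y, m, o, contrasts) {
  cell <- factor(paste(m, o), levels = c("-1 -1", "-1 1", "1 -1", "1 1"))
  ns <- as.vector(table(cell))
  if (any(ns < 2)) stop("every modality x message cell needs >= 2 subjects",
                        call. = FALSE)
  means <- tapply(y, cell, mean)
  ssw <- sum(tapply(y, cell, function(x) sum((x - mean(x))^2)))
  df2 <- length(y) - 4L
  mse <- ssw / df2
  out <- lapply(contrasts, function(cc) {
    theta <- sum(cc * means)
    denom <- mse * sum(cc^2 / ns)
    f <- if (denom == 0) {
      if (abs(theta) < .Machine$double.eps^0.5) 0 else Inf
    } else {
      theta^2 / denom
    }
    list(F = f, df1 = 1L, df2 = df2,
         p = stats::pf(f, 1, df2, lower.tail = FALSE))
  })
  out
}

#' Mixed between-within (2 x 2 x 2) ANOVA
#'
#' The factorial analysis of the trial: two between-subject factors, message
#' delivery modality (paper vs web) and message type (tailored vs
#' non-tailored), and one within-subject factor, time (pre vs post
#' intervention). With a two-level within factor the decomposition is exact
#' on derived scores: within-subject terms (time and its interactions) are
#' Type III tests on the per-subject difference `post - pre`; between-subject
#' terms on the per-subject mean. Type III sums of squares with sum-to-zero
#' coding accommodate unbalanced cell sizes; every F has df (1, N - 4).
#'
#' @param data Either a `trial_dataset` (see [simulate_cohort()]) or a data
#'   frame with columns `modality` ("paper"/"web"), `message`
#'   ("tailored"/"nontailored"), `pre` and `post` (numeric scores). Control
#'   participants in a `trial_dataset` are excluded.
#' @param outcome For a `trial_dataset`: which scale to analyse, one of
#'   [scale_factors()].
#' @return An `anova_table` data frame: `term`, `F`, `df1`, `df2`, `p`, with
#'   terms time, time:modality, time:message, time:modality:message,
#'   modality, message, modality:message.
#' @export
mixed_anova_2x2x2 <- function(data, outcome = NULL) {
  if (inherits(data, "trial_dataset")) {
    if (is.null(outcome)) stop("'outcome' scale is required", call. = FALSE)
    data <- dataset_prepost(data, outcome)
  }
  stopifnot(all(c("modality", "message", "pre", "post") %in% names(data)))
  if (!nrow(data)) stop("no intervention participants", call. = FALSE)
  if (anyNA(data[c("pre", "post")])) {
    stop("missing pre/post scores", call. = FALSE)
  }
  if (!setequal(unique(data$modality), c("paper", "web")) ||
      !setequal(unique(data$message), c("tailored", "nontailored"))) {
    stop("both levels of modality and message must be present", call. = FALSE)
  }
  m <- ifelse(data$message == "tailored", 1, -1)
  o <- ifelse(data$modality == "web", 1, -1)
  # contrast coefficients over cells (m,o) = (-,-), (-,+), (+,-), (+,+)
  cc <- list(
    mean = c(1, 1, 1, 1) / 4,
    message = c(-1, -1, 1, 1) / 4,
    modality = c(-1, 1, -1, 1) / 4,
    interaction = c(1, -1, -1, 1) / 4
  )
  within <- type3_cell_tests(data$post - data$pre, m, o, cc)
  between <- type3_cell_tests((data$pre + data$post) / 2, m, o,
                              cc[c("modality", "message", "interaction")])
  rows <- list(
    time = within$mean,
    `time:modality` = within$modality,
    `time:message` = within$message,
    `time:modality:message` = within$interaction,
    modality = between$modality,
    message = between$message,
    `modality:message` = between$interaction
  )
  out <- data.frame(
    term = names(rows),
    F = vapply(rows, `[[`, numeric(1), "F"),
    df1 = vapply(rows, `[[`, integer(1), "df1"),
    df2 = vapply(rows, `[[`, integer(1), "df2"),
    p = vapply(rows, `[[`, numeric(1), "p"),
    row.names = NULL, stringsAsFactors = FALSE
  )
  class(out) <- c("anova_table", "data.frame")
  out
}

# Wide pre/post scores for one scale, intervention participants only.
dataset_prepost <- function(dataset, outcome) {
  stopifnot(inherits(dataset, "trial_dataset"),
            outcome %in% scale_factors())
  sc <- dataset$scores
  if (!outcome %in% names(sc)) {
    stop(sprintf("scale '%s' not present in dataset scores", outcome),
         call. = FALSE)
  }
  part <- dataset$participants
  part <- part[part$arm != "control", , drop = FALSE]
  pre <- sc[sc$timepoint == "pre", c("participant_id", outcome)]
  post <- sc[sc$timepoint == "post", c("participant_id", outcome)]
  names(pre)[2] <- "pre"
  names(post)[2] <- "post"
  d <- merge(merge(part[, c("participant_id", "modality", "message")],
                   pre, by = "participant_id", all.x = TRUE),
             post, by = "participant_id", all.x = TRUE)
  incomplete <- d$participant_id[is.na(d$pre) | is.na(d$post)]
  if (length(incomplete)) {
    stop("participants missing a timepoint: ",
         paste(incomplete, collapse = ", "), call. = FALSE)
  }
  d
}

#' Full analysis report for a trial dataset
#'
#' Reproduces the shape of the study's results: baseline comparability
#' (gender chi-square across the five arms, one-way ANOVA of age), the mixed
#' 2 x 2 x 2 ANOVA for each of the seven scales, the decision-stage movement
#' dichotomization (Yates chi-square by modality and by message, excluding
#' participants decided at both timepoints), and the four FOBT chi-squares
#' (requested/returned by modality/message, Yates, with full group sizes as
#' denominators).
#'
#' @param dataset A `trial_dataset`.
#' @return An `analysis_report` list with elements `baseline`, `anovas`,
#'   `movement`, `fobt`.
#' @export
analysis_report <- function(dataset) {
  stopifnot(inherits(dataset, "trial_dataset"))
  part <- dataset$participants
  if (!nrow(part)) stop("empty dataset", call. = FALSE)

  gender_tab <- t(table(part$arm, part$gender))
  baseline <- list(
    gender = chi_square(gender_tab, yates = FALSE),
    age = one_way_anova(split(part$age, part$arm))
  )

  anovas <- lapply(stats::setNames(nm = scale_factors()), function(f) {
    mixed_anova_2x2x2(dataset, f)
  })

  iv <- part[part$arm != "control", , drop = FALSE]
  iv$movement <- mapply(classify_movement, iv$pre_stage, iv$post_stage)
  mv <- iv[iv$movement != "excluded_predecided", , drop = FALSE]
  movement_tab <- function(by) {
    tab <- table(factor(mv[[by]]),
                 factor(mv$movement,
                        levels = c("moved_to_screen", "other_movement")))
    chi_square(unclass(tab), yates = TRUE)
  }
  movement <- list(
    by_modality = movement_tab("modality"),
    by_message = movement_tab("message"),
    n_excluded_predecided = sum(iv$movement == "excluded_predecided")
  )

  fobt_tab <- function(by, event) {
    yes <- tapply(event, iv[[by]], sum)
    n <- as.vector(table(iv[[by]]))
    chi_square(cbind(yes = yes, no = n - yes), yates = TRUE)
  }
  fobt <- list(
    requested_by_modality = fobt_tab("modality", iv$fobt_requested),
    requested_by_message = fobt_tab("message", iv$fobt_requested),
    returned_by_modality = fobt_tab("modality",
                                    iv$fobt_status %in% c("early", "late")),
    returned_by_message = fobt_tab("message",
                                   iv$fobt_status %in% c("early", "late"))
  )

  structure(list(baseline = baseline, anovas = anovas, movement = movement,
                 fobt = fobt),
            class = "analysis_report")
}

#' @export
print.analysis_report <- function(x, ...) {
  cat("Baseline comparability:\n  gender: ")
  print(x$baseline$gender)
  cat(sprintf("  age: F = %.3f, df = (%d, %d), p = %.3f\n",
              x$baseline$age$F, x$baseline$age$df[1], x$baseline$age$df[2],
              x$baseline$age$p))
  cat("\nMixed 2x2x2 ANOVA (time x modality x message) per scale:\n")
  for (f in names(x$anovas)) {
    a <- x$anovas[[f]]
    cat(sprintf("  %-26s time F = %6.2f (p %.3g), txm F = %5.2f, txg F = %5.2f, txmxg F = %5.2f\n",
                f, a$F[1], a$p[1], a$F[2], a$F[3], a$F[4]))
  }
  cat("\nStage movement (Yates):\n  by modality: ")
  print(x$movement$by_modality)
  cat("  by message: ")
  print(x$movement$by_message)
  cat("\nFOBT (Yates):\n")
  for (nm in names(x$fobt)) {
    cat(sprintf("  %-24s ", nm))
    print(x$fobt[[nm]])
  }
  invisible(x)
}
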