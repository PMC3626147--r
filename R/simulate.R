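# Synthetic trial cohorts with the pre/post, between-arm structure of the
# exploratory study, for testing the analysis battery and for power / type-I
# calibration studies.

# Table of calibrated cell parameters: per scale x message x modality, the
# pre-intervention mean and SD and the post-intervention SD observed in the
# study (message/modality apply to intervention arms; control uses the
# unweighted mean across cells).
calibrated_cells <- function() {
  rows <- function(scale, pre_m, pre_sd, post_m, post_sd) {
    data.frame(
      scale = scale,
      message = c("tailored", "tailored", "nontailored", "nontailored"),
      modality = c("paper", "web", "paper", "web"),
      pre_mean = pre_m, pre_sd = pre_sd,
      post_mean = post_m, post_sd = post_sd,
      stringsAsFactors = FALSE
    )
  }
  rbind(
    rows("salience_coherence", c(16.4, 16.0, 17.0, 15.8),
         c(2.5, 2.2, 2.3, 2.4), c(16.6, 17.7, 17.6, 16.1),
         c(2.3, 2.1, 1.8, 2.5)),
    rows("cancer_worries", c(6.3, 5.2, 4.5, 5.0), c(1.6, 2.1, 2.1, 1.9),
         c(5.9, 4.3, 4.4, 5.0), c(1.9, 2.1, 1.8, 1.9)),
    rows("perceived_susceptibility", c(10.4, 10.8, 10.9, 10.8),
         c(2.1, 2.1, 1.6, 2.3), c(11.4, 12.3, 11.0, 10.9),
         c(2.1, 2.3, 2.2, 2.1)),
    rows("response_efficacy", c(7.5, 7.7, 7.4, 7.7), c(1.1, 1.1, 1.0, 1.3),
         c(8.0, 8.1, 8.1, 8.2), c(1.2, 1.1, 1.3, 1.0)),
    rows("social_influence", c(13.5, 11.7, 12.7, 12.9), c(1.9, 2.6, 2.7, 2.6),
         c(14.5, 14.9, 14.9, 14.1), c(2.0, 2.3, 2.5, 2.9)),
    rows("self_efficacy", c(11.7, 11.7, 12.5, 11.9), c(2.2, 1.9, 1.3, 1.4),
         c(12.1, 13.0, 12.4, 12.2), c(1.6, 1.9, 1.4, 1.5)),
    rows("fecal_aversion", c(9.5, 10.4, 11.2, 10.3), c(2.5, 3.0, 2.0, 2.1),
         c(10.4, 11.4, 11.9, 10.6), c(2.6, 2.8, 2.2, 2.7))
  )
}

# Which effect-map components are active per scale: the terms the study found
# significant. All scales carry a time main effect; perceived susceptibility
# and self-efficacy add time x message; social influence and salience and
# coherence add time x modality x message. time x modality is nowhere active.
effect_structure <- function() {
  list(
    salience_coherence = c("time", "time_modality_message"),
    cancer_worries = "time",
    perceived_susceptibility = c("time", "time_message"),
    response_efficacy = "time",
    social_influence = c("time", "time_modality_message"),
    self_efficacy = c("time", "time_message"),
    fecal_aversion = "time"
  )
}

# Project observed per-cell post-pre shifts onto sum-coded components
# (m = +1 tailored, o = +1 web), keeping only the active terms.
project_effects <- function(cells, active) {
  shift <- cells$post_mean - cells$pre_mean
  m <- ifelse(cells$message == "tailored", 1, -1)
  o <- ifelse(cells$modality == "web", 1, -1)
  comp <- c(
    time = mean(shift),
    time_message = sum(shift * m) / 4,
    time_modality = sum(shift * o) / 4,
    time_modality_message = sum(shift * m * o) / 4
  )
  comp[setdiff(names(comp), active)] <- 0
  as.list(comp)
}

#' Default simulation configuration
#'
#' A `sim_config` calibrated to the exploratory study: arm sizes 22/21/20/21
#' (+ 20 control), per-cell pre-intervention scale means and SDs from the
#' published descriptives, an additive effect map on the latent scale with
#' sum-to-zero coded components for the terms the study found significant
#' (time everywhere; time x message for perceived susceptibility and
#' self-efficacy; time x modality x message for social influence and salience
#' and coherence; all other components zero), pre-post correlation
#' `rho = 0.6`, FOBT request probabilities 34/42 (tailored), 28/42
#' (non-tailored) and return-given-request probabilities 22/34 and 14/28,
#' with control request behaviour driven by the post-intervention decision
#' stage. Stage transition matrices are plausible synthetic defaults (the
#' study reports no transition counts).
#'
#' @return A `sim_config` list; see [simulate_cohort()].
#' @export
default_sim_config <- function() {
  cells <- calibrated_cells()
  structure <- effect_structure()
  effects <- lapply(stats::setNames(nm = scale_factors()), function(f) {
    project_effects(cells[cells$scale == f, ], structure[[f]])
  })
  stages <- papm_stages()
  base_stage <- c(0.45, 0.10, 0.05, 0.20, 0.20)
  # rows = pre stage, cols = post stage
  t_control <- rbind(
    c(0.45, 0.50, 0.00, 0.05, 0.00),
    c(0.00, 0.90, 0.02, 0.05, 0.03),
    c(0.00, 0.00, 0.95, 0.05, 0.00),
    c(0.00, 0.00, 0.02, 0.90, 0.08),
    c(0.00, 0.00, 0.00, 0.05, 0.95))
  t_nontailored <- rbind(
    c(0.10, 0.45, 0.03, 0.22, 0.20),
    c(0.00, 0.50, 0.05, 0.20, 0.25),
    c(0.00, 0.00, 0.70, 0.20, 0.10),
    c(0.00, 0.00, 0.05, 0.55, 0.40),
    c(0.00, 0.00, 0.00, 0.05, 0.95))
  t_tailored <- rbind(
    c(0.08, 0.35, 0.02, 0.25, 0.30),
    c(0.00, 0.40, 0.04, 0.21, 0.35),
    c(0.00, 0.00, 0.60, 0.25, 0.15),
    c(0.00, 0.00, 0.04, 0.46, 0.50),
    c(0.00, 0.00, 0.00, 0.03, 0.97))
  dn <- list(stages, stages)
  dimnames(t_control) <- dimnames(t_nontailored) <- dimnames(t_tailored) <- dn

  cfg <- list(
    arm_sizes = c(control = 20, paper_nontailored = 22, paper_tailored = 21,
                  web_nontailored = 20, web_tailored = 21),
    cells = cells,
    effects = effects,
    rho = 0.6,
    age = list(mean = 61, sd = 7, min = 50, max = 76),
    stage_baseline = stats::setNames(base_stage, stages),
    stage_transitions = list(control = t_control,
                             nontailored = t_nontailored,
                             tailored = t_tailored),
    fobt = list(
      request_prob = c(tailored = 34 / 42, nontailored = 28 / 42),
      return_prob = c(tailored = 22 / 34, nontailored = 14 / 28,
                      control = 5 / 8),
      return_week_shape = 2, return_week_mean = 4.9
    )
  )
  class(cfg) <- "sim_config"
  cfg
}

#' Zero out all intervention effects in a configuration
#'
#' Convenience for type-I error studies: keeps baselines, correlation and
#' outcome probabilities but removes every additive shift, so post scores
#' share the pre-score distribution.
#'
#' @param config A `sim_config` (default [default_sim_config()]).
#' @return The modified `sim_config`.
#' @export
zero_effect_config <- function(config = default_sim_config()) {
  config$effects <- lapply(config$effects, function(e) {
    lapply(e, function(x) 0)
  })
  config
}

validate_sim_config <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (any(config$arm_sizes < 0)) stop("arm sizes must be >= 0", call. = FALSE)
  if (!all(names(config$arm_sizes) %in% study_arms())) {
    stop("unknown arm in arm_sizes", call. = FALSE)
  }
  if (any(config$cells$pre_sd <= 0) || any(config$cells$post_sd <= 0)) {
    stop("scale SDs must be positive", call. = FALSE)
  }
  if (config$rho <= -1 || config$rho >= 1) {
    stop("rho must lie in (-1, 1)", call. = FALSE)
  }
  probs <- c(config$fobt$request_prob, config$fobt$return_prob,
             config$stage_baseline, unlist(config$stage_transitions))
  if (any(probs < 0 | probs > 1)) {
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  }
  for (tm in config$stage_transitions) {
    if (any(abs(rowSums(tm) - 1) > 1e-8)) {
      stop("stage transition rows must sum to 1", call. = FALSE)
    }
  }
  invisible(config)
}

# Split an integer scale score (within [k, 5k]) into k item responses in 1..5
# that sum to it: equal base value, remainder added to the leading items.
score_to_items <- function(score, k) {
  base <- score %/% k
  r <- score %% k
  v <- rep(base, k)
  if (r > 0) v[seq_len(r)] <- v[seq_len(r)] + 1L
  as.integer(v)
}

#' Simulate a synthetic trial cohort
#'
#' Latent pre/post scale scores are drawn per participant from a bivariate
#' normal with the configured cell means and SDs and pre-post correlation
#' `rho`; the post mean adds the cell's effect shift (sum of the active
#' sum-coded components). Latent scores are rounded, clipped to the scale
#' bounds, and disaggregated into integer item responses that preserve the
#' score sum. PAPM stages follow the baseline distribution and the arm's
#' transition matrix; FOBT requests are Bernoulli per message type (control
#' participants count as requesters exactly when their post stage is
#' decided_to_act), returns are Bernoulli given request, and return weeks are
#' gamma distributed (truncated at 12 weeks for returners).
#'
#' @param config A `sim_config`, e.g. [default_sim_config()].
#' @param seed Integer seed; the dataset is fully reproducible from it.
#' @param scales Which scales to simulate (default all seven).
#' @return A `trial_dataset` list: `participants` (one row each: id, arm,
#'   modality, message, age, gender, pre/post stage, FOBT request/return
#'   fields), `scores` (long: participant, timepoint, one column per scale),
#'   `responses` (survey rows: participant, timepoint, stage code, item
#'   columns). Attribute `clip_rate` reports the fraction of latent scores
#'   clipped at the bounds.
#' @export
simulate_cohort <- function(config = default_sim_config(), seed = 1,
                            scales = scale_factors()) {
  validate_sim_config(config)
  stopifnot(all(scales %in% scale_factors()))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)

  sizes <- config$arm_sizes[config$arm_sizes > 0]
  arms <- rep(names(sizes), sizes)
  n <- length(arms)
  if (!n) stop("configuration allocates no participants", call. = FALSE)
  ids <- sprintf("P%04d", seq_len(n))
  age <- pmin(pmax(round(stats::rnorm(n, config$age$mean, config$age$sd)),
                   config$age$min), config$age$max)
  gender <- sample(c("male", "female"), n, replace = TRUE)
  modality <- arm_modality(arms)
  message_type <- arm_message(arms)

  stages <- papm_stages()
  pre_stage <- sample(stages, n, replace = TRUE, prob = config$stage_baseline)
  post_stage <- vapply(seq_len(n), function(i) {
    tm <- if (arms[i] == "control") "control" else message_type[i]
    trans <- config$stage_transitions[[tm]]
    sample(stages, 1, prob = trans[pre_stage[i], ])
  }, character(1))

  registry <- phm_scales()
  n_clipped <- 0L
  n_latent <- 0L
  score_cols <- list()
  item_cols <- list()
  cell_key <- paste(message_type, modality)
  for (f in scales) {
    k <- length(registry[[f]]$items)
    sub <- config$cells[config$cells$scale == f, ]
    idx <- match(cell_key, paste(sub$message, sub$modality)) # NA for control
    pick <- function(col) {
      ifelse(is.na(idx), mean(sub[[col]]), sub[[col]][idx])
    }
    pre_m <- pick("pre_mean")
    pre_s <- pick("pre_sd")
    post_s <- pick("post_sd")
    eff <- config$effects[[f]]
    m <- ifelse(message_type == "tailored", 1,
                ifelse(message_type == "nontailored", -1, 0))
    o <- ifelse(modality == "web", 1, ifelse(modality == "paper", -1, 0))
    interv <- arms != "control"
    shift <- ifelse(interv,
                    eff$time + eff$time_message * m + eff$time_modality * o +
                      eff$time_modality_message * m * o,
                    0)
    z1 <- stats::rnorm(n)
    z2 <- stats::rnorm(n)
    lat_pre <- pre_m + pre_s * z1
    lat_post <- (pre_m + shift) +
      post_s * (config$rho * z1 + sqrt(1 - config$rho^2) * z2)
    to_score <- function(lat) {
      s <- round(lat)
      clipped <- s < k | s > 5 * k
      n_clipped <<- n_clipped + sum(clipped)
      n_latent <<- n_latent + length(s)
      as.integer(pmin(pmax(s, k), 5 * k))
    }
    s_pre <- to_score(lat_pre)
    s_post <- to_score(lat_post)
    score_cols[[f]] <- list(pre = s_pre, post = s_post)
    # emit RAW item responses: reverse-coded items are stored unreversed in
    # the survey, so scoring them back through 6 - v recovers the score
    rev_cols <- which(registry[[f]]$items %in% registry[[f]]$reverse_coded)
    to_raw <- function(s) {
      m <- t(vapply(s, score_to_items, integer(k), k = k))
      m[, rev_cols] <- 6L - m[, rev_cols]
      m
    }
    item_cols[[f]] <- list(pre = to_raw(s_pre), post = to_raw(s_post))
  }

  u <- stats::runif(n)
  requested <- ifelse(arms == "control",
                      post_stage == "decided_to_act",
                      u < config$fobt$request_prob[
                        ifelse(message_type == "none", "tailored",
                               message_type)])
  ret_key <- ifelse(arms == "control", "control", message_type)
  returned <- requested &
    stats::runif(n) < config$fobt$return_prob[ret_key]
  rate <- config$fobt$return_week_shape / config$fobt$return_week_mean
  week <- rep(NA_real_, n)
  for (i in which(returned)) {
    w <- stats::rgamma(1, shape = config$fobt$return_week_shape, rate = rate)
    while (w > 12) {
      w <- stats::rgamma(1, shape = config$fobt$return_week_shape,
                         rate = rate)
    }
    week[i] <- max(round(w, 1), 0.1)
  }
  fobt_status <- vapply(seq_len(n), function(i) {
    classify_fobt(requested[i], week[i])$status
  }, character(1))

  participants <- data.frame(
    participant_id = ids, arm = arms, modality = modality,
    message = message_type, age = age, gender = gender,
    pre_stage = pre_stage, post_stage = post_stage,
    fobt_requested = requested, fobt_return_week = week,
    fobt_status = fobt_status,
    stringsAsFactors = FALSE
  )

  mk_scores <- function(tp) {
    out <- data.frame(participant_id = ids, timepoint = tp,
                      stringsAsFactors = FALSE)
    for (f in scales) out[[f]] <- score_cols[[f]][[tp]]
    out
  }
  scores <- rbind(mk_scores("pre"), mk_scores("post"))

  responses <- NULL
  if (setequal(scales, scale_factors())) {
    mk_resp <- function(tp) {
      items <- do.call(cbind, lapply(scale_factors(),
                                     function(f) item_cols[[f]][[tp]]))
      colnames(items) <- paste0("item_", seq_len(ncol(items)))
      cbind(data.frame(participant_id = ids, timepoint = tp,
                       stage = match(if (tp == "pre") pre_stage else
                         post_stage, stages),
                       stringsAsFactors = FALSE),
            as.data.frame(items))
    }
    responses <- rbind(mk_resp("pre"), mk_resp("post"))
  }

  structure(list(participants = participants, scores = scores,
                 responses = responses, config = config, seed = seed),
            class = "trial_dataset",
            clip_rate = if (n_latent) n_clipped / n_latent else 0)
}

#' @export
print.trial_dataset <- function(x, ...) {
  cat(sprintf("<trial_dataset: %d participants (%s), seed %s>\n",
              nrow(x$participants),
              paste(sprintf("%s=%d", names(table(x$participants$arm)),
                            as.vector(table(x$participants$arm))),
                    collapse = ", "),
              format(x$seed)))
  invisible(x)
}

#' Repeated simulate-and-analyse study
#'
#' Simulates `n_reps` cohorts from `config` and runs the mixed 2 x 2 x 2
#' ANOVA on each requested scale, recording per-term rejection at `alpha` and
#' the recovered intervention cell means. Used for type-I error calibration
#' (with [zero_effect_config()]), power analysis, and bias checks.
#'
#' @param config A `sim_config`.
#' @param n_reps Number of replicates (>= 1).
#' @param scales Scales to analyse (default all seven).
#' @param alpha Two-sided significance level (default 0.05).
#' @param seed Integer seed for the study; replicate r uses `seed + r`.
#' @return A `recovery_report` list: `rejection_rates` (matrix scale x term),
#'   `mean_cell_means` / `expected_cell_means` (per scale: 2 x 2 matrices of
#'   recovered and config-implied post-intervention cell means), `n_reps`,
#'   `alpha`.
#' @export
parameter_recovery_study <- function(config = default_sim_config(),
                                     n_reps = 100,
                                     scales = scale_factors(),
                                     alpha = 0.05, seed = 1) {
  stopifnot(n_reps >= 1)
  validate_sim_config(config)
  terms <- c("time", "time:modality", "time:message",
             "time:modality:message", "modality", "message",
             "modality:message")
  reject <- array(0, dim = c(length(scales), length(terms)),
                  dimnames = list(scales, terms))
  post_sum <- lapply(stats::setNames(nm = scales), function(f) {
    matrix(0, 2, 2, dimnames = list(message = c("tailored", "nontailored"),
                                    modality = c("paper", "web")))
  })
  for (r in seq_len(n_reps)) {
    ds <- simulate_cohort(config, seed = seed + r, scales = scales)
    for (f in scales) {
      at <- mixed_anova_2x2x2(ds, f)
      reject[f, ] <- reject[f, ] + (at$p[match(terms, at$term)] < alpha)
      d <- dataset_prepost(ds, f)
      cm <- tapply(d$post, list(d$message, d$modality), mean)
      post_sum[[f]] <- post_sum[[f]] +
        cm[c("tailored", "nontailored"), c("paper", "web")]
    }
  }
  expected <- lapply(stats::setNames(nm = scales), function(f) {
    cells <- config$cells[config$cells$scale == f, ]
    eff <- config$effects[[f]]
    m <- ifelse(cells$message == "tailored", 1, -1)
    o <- ifelse(cells$modality == "web", 1, -1)
    mu <- cells$pre_mean + eff$time + eff$time_message * m +
      eff$time_modality * o + eff$time_modality_message * m * o
    out <- matrix(NA_real_, 2, 2,
                  dimnames = list(message = c("tailored", "nontailored"),
                                  modality = c("paper", "web")))
    for (i in seq_len(nrow(cells))) {
      out[cells$message[i], cells$modality[i]] <- mu[i]
    }
    out
  })
  structure(list(
    rejection_rates = reject / n_reps,
    mean_cell_means = lapply(post_sum, function(m) m / n_reps),
    expected_cell_means = expected,
    n_reps = n_reps, alpha = alpha),
    class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat(sprintf("<recovery_report: %d reps, alpha = %.3f>\n", x$n_reps,
              x$alpha))
  cat("Rejection rates:\n")
  print(round(x$rejection_rates, 3))
  invisible(x)
}
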