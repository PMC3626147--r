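test_that("the default configuration carries the published calibration", {
  cfg <- default_sim_config()
  cells <- cfg$cells
  pick <- function(scale, msg, mod, col) {
    cells[cells$scale == scale & cells$message == msg &
            cells$modality == mod, col]
  }
  expect_equal(pick("salience_coherence", "tailored", "web", "pre_mean"),
               16.0)
  expect_equal(pick("social_influence", "tailored", "web", "pre_mean"), 11.7)
  expect_equal(cfg$fobt$request_prob[["nontailored"]], 28 / 42)
  expect_equal(cfg$fobt$request_prob[["tailored"]], 34 / 42)
  expect_equal(cfg$arm_sizes, c(control = 20, paper_nontailored = 22,
                                paper_tailored = 21, web_nontailored = 20,
                                web_tailored = 21))
  # every configured mean lies within its scale's bounds
  k <- vapply(phm_scales(), function(s) length(s$items), integer(1))
  for (i in seq_len(nrow(cells))) {
    ki <- k[[cells$scale[i]]]
    expect_gte(cells$pre_mean[i], ki)
    expect_lte(cells$pre_mean[i], 5 * ki)
  }
  # effect map: time everywhere; time x message only for susceptibility and
  # self-efficacy; three-way only for social influence and salience/coherence;
  # time x modality nowhere
  for (f in scale_factors()) {
    e <- cfg$effects[[f]]
    expect_equal(e$time_modality, 0)
    expect_equal(e$time_message != 0,
                 f %in% c("perceived_susceptibility", "self_efficacy"))
    expect_equal(e$time_modality_message != 0,
                 f %in% c("social_influence", "salience_coherence"))
    expect_gt(abs(e$time), 0)
  }
  # susceptibility time x message component projected from the cell shifts
  expect_equal(cfg$effects$perceived_susceptibility$time_message,
               ((1.0 + 1.5) - (0.1 + 0.1)) / 4)
})

test_that("simulation is byte-identical under a fixed seed", {
  cfg <- default_sim_config()
  expect_identical(simulate_cohort(cfg, seed = 9),
                   simulate_cohort(cfg, seed = 9))
  d1 <- simulate_cohort(cfg, seed = 9)
  d2 <- simulate_cohort(cfg, seed = 10)
  expect_false(identical(d1$scores, d2$scores))
})

test_that("simulated scores respect bounds; clipping is rare and reported", {
  ds <- simulate_cohort(default_sim_config(), seed = 21)
  k <- vapply(phm_scales(), function(s) length(s$items), integer(1))
  for (f in scale_factors()) {
    expect_true(all(ds$scores[[f]] >= k[[f]] & ds$scores[[f]] <= 5 * k[[f]]))
  }
  items <- as.matrix(ds$responses[, paste0("item_", 1:22)])
  expect_true(all(items >= 1 & items <= 5))
  # item responses reconstruct the stored scale scores exactly
  scored <- score_survey(ds$responses)
  key <- paste(ds$scores$participant_id, ds$scores$timepoint)
  skey <- paste(scored$participant_id, scored$timepoint)
  expect_equal(scored$fecal_aversion,
               ds$scores$fecal_aversion[match(skey, key)])
  clip <- attr(ds, "clip_rate")
  expect_true(is.numeric(clip) && clip >= 0)
  expect_lt(clip, 0.05) # several published cell means sit ~1.5 SD from a
  # bound, so a normal latent necessarily clips a few percent of draws
})

test_that("zero-effect simulation has no pre/post drift at large n", {
  cfg <- zero_effect_config()
  cfg$arm_sizes <- c(control = 0, paper_nontailored = 2500,
                     paper_tailored = 2500, web_nontailored = 2500,
                     web_tailored = 2500)
  ds <- simulate_cohort(cfg, seed = 22, scales = "social_influence")
  d <- merge(ds$scores[ds$scores$timepoint == "pre",
                       c("participant_id", "social_influence")],
             ds$scores[ds$scores$timepoint == "post",
                       c("participant_id", "social_influence")],
             by = "participant_id")
  diff <- d[[3]] - d[[2]]
  se <- sd(diff) / sqrt(length(diff))
  expect_lt(abs(mean(diff)), 3 * se)
})

test_that("the calibrated generator recovers its configured cell mean", {
  cfg <- default_sim_config()
  cfg$arm_sizes <- c(control = 0, paper_nontailored = 10000,
                     paper_tailored = 10000, web_nontailored = 10000,
                     web_tailored = 10000)
  ds <- simulate_cohort(cfg, seed = 23, scales = "social_influence")
  part <- ds$participants
  wt <- part$participant_id[part$arm == "web_tailored"]
  post <- ds$scores[ds$scores$timepoint == "post" &
                      ds$scores$participant_id %in% wt, "social_influence"]
  e <- cfg$effects$social_influence
  implied <- 11.7 + e$time + e$time_message + e$time_modality +
    e$time_modality_message # web/tailored cell: m = o = +1
  se <- sd(post) / sqrt(length(post))
  # rounding/clipping keeps the realized mean within a fraction of a point
  expect_lt(abs(mean(post) - implied), max(3 * se, 0.2))
})

test_that("recovered effect estimates increase with the injected effect", {
  grid <- c(0, 0.5, 1, 2)
  est <- vapply(seq_along(grid), function(i) {
    cfg <- zero_effect_config()
    cfg$effects$self_efficacy$time_message <- grid[i]
    cfg$arm_sizes <- c(control = 0, paper_nontailored = 100,
                       paper_tailored = 100, web_nontailored = 100,
                       web_tailored = 100)
    ds <- simulate_cohort(cfg, seed = 100, scales = "self_efficacy")
    d <- crctailor:::dataset_prepost(ds, "self_efficacy")
    diff <- d$post - d$pre
    m <- ifelse(d$message == "tailored", 1, -1)
    mean(diff[m == 1]) - mean(diff[m == -1])
  }, numeric(1))
  expect_true(all(diff(est) > 0))
})

test_that("invalid configurations fail before sampling", {
  cfg <- default_sim_config()
  cfg$rho <- 1.2
  expect_error(simulate_cohort(cfg, seed = 1), "rho")
  cfg <- default_sim_config()
  cfg$fobt$request_prob[["tailored"]] <- 1.4
  expect_error(simulate_cohort(cfg, seed = 1), "probabilities")
  cfg <- default_sim_config()
  cfg$cells$pre_sd[1] <- 0
  expect_error(simulate_cohort(cfg, seed = 1), "SD")
  cfg <- default_sim_config()
  cfg$stage_transitions$control[1, ] <- c(0.5, 0.6, 0, 0, 0)
  expect_error(simulate_cohort(cfg, seed = 1), "sum to 1")
})

test_that("parameter recovery reports rejection rates and unbiased means", {
  cfg <- default_sim_config()
  rec <- parameter_recovery_study(cfg, n_reps = 30,
                                  scales = "perceived_susceptibility",
                                  seed = 30)
  expect_equal(dim(rec$rejection_rates), c(1L, 7L))
  # time shift 0.675 at the trial's n gives high but not total power
  expect_gte(rec$rejection_rates["perceived_susceptibility", "time"], 0.8)
  got <- rec$mean_cell_means$perceived_susceptibility
  want <- rec$expected_cell_means$perceived_susceptibility
  # 30 reps x ~21/cell: SE of a cell-mean average ~ 2.2/sqrt(630) ~ 0.09
  expect_lt(max(abs(got - want)), 0.3)
})
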