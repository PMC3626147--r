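# Shared fixtures and independent oracles for the test suite.

# Brute-force scale scoring: per-item loop, no vectorization shared with the
# implementation.
oracle_score <- function(responses, scale) {
  total <- 0L
  for (item in scale$items) {
    v <- responses[[item]]
    if (item %in% scale$reverse_coded) v <- 6L - v
    total <- total + v
  }
  total
}

# Cronbach's alpha straight from the covariance matrix:
# alpha = k/(k-1) * (1 - tr(C) / sum(C)).
oracle_alpha <- function(m) {
  C <- cov(m)
  k <- ncol(m)
  k / (k - 1) * (1 - sum(diag(C)) / sum(C))
}

# Textbook Pearson chi-square, cell by cell.
oracle_chisq <- function(m) {
  E <- outer(rowSums(m), colSums(m)) / sum(m)
  sum((m - E)^2 / E)
}

# Independent mixed-ANOVA oracle: Type III F values from sum-coded linear
# models on the difference and mean scores, via car::Anova.
oracle_mixed_anova <- function(d) {
  op <- options(contrasts = c("contr.sum", "contr.poly"))
  on.exit(options(op))
  M <- factor(d$modality)
  G <- factor(d$message)
  aw <- car::Anova(lm((d$post - d$pre) ~ M * G), type = 3)
  ab <- car::Anova(lm(((d$pre + d$post) / 2) ~ M * G), type = 3)
  c(time = aw["(Intercept)", "F value"],
    `time:modality` = aw["M", "F value"],
    `time:message` = aw["G", "F value"],
    `time:modality:message` = aw["M:G", "F value"],
    modality = ab["M", "F value"],
    message = ab["G", "F value"],
    `modality:message` = ab["M:G", "F value"])
}

# Random unbalanced pre/post dataset in the data-frame form accepted by
# mixed_anova_2x2x2().
random_prepost <- function(min_n = 3, max_n = 12) {
  ns <- sample(min_n:max_n, 4, replace = TRUE)
  data.frame(
    modality = rep(c("paper", "paper", "web", "web"), ns),
    message = rep(c("tailored", "nontailored", "tailored", "nontailored"),
                  ns),
    pre = rnorm(sum(ns), 10, 2),
    post = rnorm(sum(ns), 11, 2)
  )
}

# Uniform random full response vector (named by item id) for one scale.
random_responses <- function(scale) {
  setNames(sample(1:5, length(scale$items), replace = TRUE), scale$items)
}

# All six tailoring responses at a given level (or random).
tailoring_levels <- function(levels = sample(1:5, 6, replace = TRUE)) {
  setNames(as.integer(levels), tailorable_factors())
}
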