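lib <- default_message_library()

test_that("the default library is complete and well toned", {
  expect_equal(nrow(lib), 30L) # 6 factors x 5 levels
  expect_equal(nrow(validate_library(lib)), 0L)
  expect_false("cancer_worries" %in% lib$factor)
  # tone gradient: reinforcing at 4-5, motivating at 1-3, no switchbacks
  for (f in tailorable_factors()) {
    tones <- lib$tone[lib$factor == f][order(lib$level[lib$factor == f],
                                             decreasing = TRUE)]
    expect_equal(tones, c("reinforcing", "reinforcing", "motivating",
                          "motivating", "motivating"))
  }
})

test_that("validate_library reports missing cells, intruders and bad tokens", {
  broken <- lib[!(lib$factor == "self_efficacy" & lib$level == 2), ]
  f <- validate_library(broken)
  expect_equal(f$type, "missing_cell")
  expect_equal(f$factor, "self_efficacy")
  expect_equal(f$level, 2L)

  intruder <- rbind(lib, data.frame(factor = "cancer_worries", level = 3,
                                    tone = "motivating",
                                    template = "[Name], try not to worry."))
  expect_true("non_tailorable_factor" %in% validate_library(intruder)$type)

  bad <- lib
  bad$template[1] <- "[Doctor] recommends screening."
  types <- validate_library(bad)$type
  expect_true("unknown_token" %in% types)
})

test_that("select_variant keys on the (direction-corrected) response", {
  v <- select_variant(lib, "response_efficacy", 5)
  expect_match(v$template, "You're absolutely right", fixed = TRUE)
  expect_equal(v$tone, "reinforcing")
  v3 <- select_variant(lib, "response_efficacy", 3)
  expect_match(v3$template, "you're not sure that colon cancer screening is effective",
               fixed = TRUE)
  expect_equal(v3$tone, "motivating")
  expect_error(select_variant(lib, "response_efficacy", 6), "1..5")
  expect_error(select_variant(lib, "cancer_worries", 3), "not a tailorable")
  # fecal aversion's tailoring statement is reverse keyed: strong
  # disagreement with "distasteful" is screening-consistent
  expect_equal(select_variant(lib, "fecal_aversion", 1)$tone, "reinforcing")
  expect_equal(select_variant(lib, "fecal_aversion", 5)$tone, "motivating")
  incomplete <- lib[-which(lib$factor == "social_influence" & lib$level == 4),
                    ]
  expect_error(select_variant(incomplete, "social_influence", 4),
               "incomplete")
})

test_that("priority_factors follows the stage rule table and partitions", {
  expect_equal(priority_factors("never_heard"),
               c("salience_coherence", "perceived_susceptibility"))
  expect_equal(priority_factors("not_considered"),
               c("perceived_susceptibility", "response_efficacy"))
  expect_equal(priority_factors("decided_against"),
               c("perceived_susceptibility", "self_efficacy"))
  expect_equal(priority_factors("undecided"),
               c("salience_coherence", "self_efficacy"))
  expect_equal(priority_factors("decided_to_act"),
               c("response_efficacy", "self_efficacy"))
  for (stage in papm_stages()) {
    pair <- priority_factors(stage)
    expect_length(pair, 2)
    expect_setequal(c(pair, setdiff(tailorable_factors(), pair)),
                    tailorable_factors())
  }
  expect_error(priority_factors("contemplation"), "unknown")
})

test_that("personalize substitutes every token and rejects unknown ones", {
  expect_equal(personalize("As you are [age],", "Greg", 57), "As you are 57,")
  expect_equal(personalize("[Name], hello [Name].", "Ann", 60),
               "Ann, hello Ann.")
  expect_equal(personalize("no tokens here", "Ann", 60), "no tokens here")
  expect_error(personalize("[Nickname]", "Ann", 60), "unknown")
  expect_error(personalize("[Name]", "Ann", -3), "age")
})

test_that("assemble_bundle reproduces the worked example", {
  b <- assemble_bundle(lib, "Greg", 57, "not_considered",
                       tailoring_levels(c(5, 4, 3, 4, 2, 2)))
  # reinforcing response-efficacy feedback leads; the motivating
  # susceptibility message follows
  expect_equal(names(b$chunk1),
               c("response_efficacy", "perceived_susceptibility"))
  expect_match(b$chunk1[["response_efficacy"]],
               "^Greg, you've told us that you believe colon cancer screening is effective")
  expect_match(b$chunk1[["perceived_susceptibility"]],
               "you're not sure whether you're at risk", fixed = TRUE)
  # chunk 2 covers the remaining four factors in instrument order
  expect_equal(names(b$chunk2),
               c("salience_coherence", "social_influence", "self_efficacy",
                 "fecal_aversion"))
  expect_false(grepl("[][]", format(b)))
})

test_that("uniformly screening-consistent answers get all-reinforcing text", {
  # fecal aversion is reverse keyed, so its consistent raw answer is 1
  consistent <- tailoring_levels(c(5, 5, 5, 5, 5, 1))
  b <- assemble_bundle(lib, "Dawn", 63, "undecided", consistent)
  msgs <- c(b$chunk1, b$chunk2)
  for (f in names(msgs)) {
    lev <- if (f == "fecal_aversion") 6 - consistent[[f]] else consistent[[f]]
    expect_equal(lib$tone[lib$factor == f & lib$level == lev], "reinforcing")
  }
})

test_that("bundles always partition the tailorable factors without tokens", {
  set.seed(31)
  for (i in 1:100) {
    stage <- sample(papm_stages(), 1)
    b <- assemble_bundle(lib, "Pat", sample(50:76, 1), stage,
                         tailoring_levels())
    expect_setequal(c(names(b$chunk1), names(b$chunk2)),
                    tailorable_factors())
    expect_length(intersect(names(b$chunk1), names(b$chunk2)), 0)
    expect_setequal(names(b$chunk1), priority_factors(stage))
    expect_false(any(grepl("[][]", c(b$chunk1, b$chunk2))))
  }
  expect_error(assemble_bundle(lib, "Pat", 60, "undecided",
                               tailoring_levels()[-2]),
               "social_influence")
})

test_that("generic bundle is a fixed, impersonal statement sequence", {
  g1 <- generic_bundle()
  expect_match(g1[1], "People can have colon polyps or cancer", fixed = TRUE)
  expect_identical(g1, generic_bundle())
  expect_false(any(grepl("[][]", g1)))
})

test_that("message libraries round-trip through JSON exactly", {
  path <- withr::local_tempfile(fileext = ".json")
  write_message_library(lib, path)
  back <- read_message_library(path)
  expect_identical(as.data.frame(back), as.data.frame(lib))
})
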