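# Tailored message assembly: library handling, stage priority rules,
# personalization and chunked bundle construction.

#' Read a message library from a JSON file
#'
#' A library holds one message variant per (factor, level) cell for the six
#' tailorable factors: 30 variants. Levels key to the direction-corrected
#' response (1-5) to the factor's designated tailoring statement; levels 4-5
#' carry a reinforcing tone, 1-3 a motivating tone.
#'
#' @param path Path to a JSON file with a `variants` array of objects with
#'   fields `factor`, `level`, `tone`, `template`.
#' @return A `message_library`: data frame with columns `factor`, `level`,
#'   `tone`, `template`.
#' @seealso [default_message_library()], [validate_library()],
#'   [write_message_library()]
#' @export
read_message_library <- function(path) {
  raw <- jsonlite::read_json(path)
  if (is.null(raw$variants)) stop("library file has no 'variants' field",
                                  call. = FALSE)
  lib <- data.frame(
    factor = vapply(raw$variants, `[[`, "", "factor"),
    level = vapply(raw$variants, function(v) as.integer(v$level), integer(1)),
    tone = vapply(raw$variants, `[[`, "", "tone"),
    template = vapply(raw$variants, `[[`, "", "template"),
    stringsAsFactors = FALSE
  )
  class(lib) <- c("message_library", "data.frame")
  lib
}

#' Write a message library to JSON
#'
#' Round-trips exactly with [read_message_library()].
#'
#' @param library A `message_library`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_message_library <- function(library, path) {
  variants <- lapply(seq_len(nrow(library)), function(i) {
    list(factor = library$factor[i], level = library$level[i],
         tone = library$tone[i], template = library$template[i])
  })
  jsonlite::write_json(list(variants = variants), path, auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}

#' The packaged default message library
#'
#' The response-efficacy variants are the published library excerpt; the
#' variants for the other five factors are synthetic paraphrases of the
#' generic information statements (see [generic_bundle()]) and are intended
#' as replaceable content.
#'
#' @return A `message_library`.
#' @export
default_message_library <- function() {
  read_message_library(system.file("extdata", "message_library.json",
                                   package = "crctailor", mustWork = TRUE))
}

#' Validate a message library
#'
#' Report-only check for missing (factor, level) cells, duplicate cells,
#' variants for non-tailorable factors (e.g. cancer worries), unknown
#' personalization tokens, and tone inconsistencies (levels 4-5 must be
#' reinforcing, 1-3 motivating).
#'
#' @param library A `message_library`.
#' @return Data frame of findings with columns `type`, `factor`, `level`,
#'   `detail`; zero rows when the library is valid.
#' @export
validate_library <- function(library) {
  findings <- list()
  add <- function(type, factor, level, detail) {
    findings[[length(findings) + 1]] <<- data.frame(
      type = type, factor = factor, level = level, detail = detail,
      stringsAsFactors = FALSE)
  }
  intruders <- setdiff(unique(library$factor), tailorable_factors())
  for (f in intruders) {
    add("non_tailorable_factor", f, NA_integer_,
        "variants present for a factor outside the tailorable set")
  }
  for (f in tailorable_factors()) {
    for (lev in 1:5) {
      n <- sum(library$factor == f & library$level == lev)
      if (n == 0) add("missing_cell", f, lev, "no variant for this cell")
      if (n > 1) add("duplicate_cell", f, lev,
                     sprintf("%d variants for this cell", n))
    }
  }
  for (i in seq_len(nrow(library))) {
    toks <- template_tokens(library$template[i])
    bad <- setdiff(toks, c("Name", "age"))
    if (length(bad)) {
      add("unknown_token", library$factor[i], library$level[i],
          paste0("unknown token(s): ",
                 paste0("[", bad, "]", collapse = ", ")))
    }
    expected <- if (library$level[i] >= 4) "reinforcing" else "motivating"
    if (!identical(library$tone[i], expected)) {
      add("tone_mismatch", library$factor[i], library$level[i],
          sprintf("tone '%s' but level %d implies '%s'",
                  library$tone[i], library$level[i], expected))
    }
  }
  if (!length(findings)) {
    return(data.frame(type = character(), factor = character(),
                      level = integer(), detail = character(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, findings)
}

template_tokens <- function(template) {
  m <- gregexpr("\\[([^][]*)\\]", template)[[1]]
  if (m[1] == -1) return(character())
  starts <- as.integer(m)
  lens <- attr(m, "match.length")
  substring(template, starts + 1, starts + lens - 2)
}

#' Select the message variant for a factor and tailoring response
#'
#' For factors whose designated tailoring statement is reverse keyed (fecal
#' aversion: agreement is screening-inconsistent), the raw response is first
#' direction-corrected through `6 - v`, so that screening-consistent answers
#' always receive a reinforcing-tone variant.
#'
#' @param library A `message_library`.
#' @param factor One of [tailorable_factors()].
#' @param tailoring_response Raw Likert response (1-5) to the factor's
#'   tailoring statement.
#' @return One-row `message_library` data frame (the variant).
#' @examples
#' lib <- default_message_library()
#' select_variant(lib, "response_efficacy", 5)$tone # "reinforcing"
#' @export
select_variant <- function(library, factor, tailoring_response) {
  if (!factor %in% tailorable_factors()) {
    stop(sprintf("'%s' is not a tailorable factor", factor), call. = FALSE)
  }
  check_likert(tailoring_response, "tailoring response")
  level <- tailoring_level(factor, tailoring_response)
  hit <- library$factor == factor & library$level == level
  if (sum(hit) != 1) {
    stop(sprintf(
      "library is incomplete: %d variant(s) for (%s, level %d)",
      sum(hit), factor, level), call. = FALSE)
  }
  library[hit, , drop = FALSE]
}

# Direction-correct the raw tailoring response where the designated tailoring
# item is itself reverse coded.
tailoring_level <- function(factor, response) {
  sc <- phm_scales()[[factor]]
  if (!is.na(sc$tailoring_item) && sc$tailoring_item %in% sc$reverse_coded) {
    6L - as.integer(response)
  } else {
    as.integer(response)
  }
}

#' Priority PHM factors for a PAPM decision stage
#'
#' The two factors most strongly associated with movement out of each stage;
#' their messages form chunk 1 of a tailored bundle (primacy effect).
#'
#' @param stage One of [papm_stages()].
#' @return Character vector of two factors, in rule listing order.
#' @examples
#' priority_factors("never_heard")
#' @export
priority_factors <- function(stage) {
  rules <- list(
    never_heard = c("salience_coherence", "perceived_susceptibility"),
    not_considered = c("perceived_susceptibility", "response_efficacy"),
    decided_against = c("perceived_susceptibility", "self_efficacy"),
    undecided = c("salience_coherence", "self_efficacy"),
    decided_to_act = c("response_efficacy", "self_efficacy")
  )
  stage <- as.character(stage)
  if (!stage %in% names(rules)) {
    stop(sprintf("unknown PAPM stage '%s'", stage), call. = FALSE)
  }
  rules[[stage]]
}

#' Substitute personalization tokens in a message template
#'
#' Supported tokens are `[Name]` and `[age]`; any other bracketed token is an
#' error, and no brackets remain in the output.
#'
#' @param template Template text.
#' @param name Recipient's name.
#' @param age Recipient's age in whole years.
#' @return Personalized text.
#' @examples
#' personalize("As you are [age],", "Greg", 57)
#' @export
personalize <- function(template, name, age) {
  stopifnot(length(template) == 1, length(name) == 1, length(age) == 1)
  if (!is.finite(age) || age != as.integer(age) || age < 0) {
    stop("age must be a non-negative whole number", call. = FALSE)
  }
  unknown <- setdiff(template_tokens(template), c("Name", "age"))
  if (length(unknown)) {
    stop("unknown personalization token(s): ",
         paste0("[", unknown, "]", collapse = ", "), call. = FALSE)
  }
  out <- gsub("[Name]", name, template, fixed = TRUE)
  gsub("[age]", as.character(as.integer(age)), out, fixed = TRUE)
}

#' Assemble a tailored feedback bundle for one respondent
#'
#' Chunk 1 holds the personalized variants for the two priority factors of
#' the respondent's PAPM stage (see [priority_factors()]); chunk 2 holds the
#' remaining four tailorable factors in instrument listing order. Within
#' chunk 1, a reinforcing-tone message is presented before a motivating one
#' (ties keep the stage rule's order), so the bundle opens by affirming
#' screening-consistent beliefs before correcting inconsistent ones.
#' Concatenation is deterministic: messages are joined verbatim, one
#' paragraph each, with no manual editing. Use `override` to substitute
#' hand-curated copy for the whole bundle.
#'
#' @param library A `message_library`.
#' @param name,age Recipient's name and age (whole years).
#' @param stage One of [papm_stages()].
#' @param tailoring_responses Named integer vector: raw 1-5 response to each
#'   tailorable factor's designated tailoring statement; names must cover
#'   [tailorable_factors()].
#' @param override Optional character scalar of curated replacement text; when
#'   given it is stored verbatim as the bundle's display text.
#' @return A `tailored_bundle`: list with `name`, `age`, `stage`, `chunk1`,
#'   `chunk2` (named character vectors of personalized messages, names are
#'   factors) and `override` (or `NULL`).
#' @examples
#' lib <- default_message_library()
#' b <- assemble_bundle(lib, "Greg", 57, "not_considered",
#'   c(salience_coherence = 5, social_influence = 4,
#'     perceived_susceptibility = 3, response_efficacy = 4,
#'     self_efficacy = 2, fecal_aversion = 2))
#' names(b$chunk1)
#' @export
assemble_bundle <- function(library, name, age, stage, tailoring_responses,
                            override = NULL) {
  absent <- setdiff(tailorable_factors(), names(tailoring_responses))
  if (length(absent)) {
    stop("tailoring responses missing for factor(s): ",
         paste(absent, collapse = ", "), call. = FALSE)
  }
  pri <- priority_factors(stage)
  variants <- lapply(tailorable_factors(), function(f) {
    select_variant(library, f, tailoring_responses[[f]])
  })
  names(variants) <- tailorable_factors()
  # chunk 1: stage priority pair, reinforcing tone first (stable)
  tones <- vapply(variants[pri], `[[`, "", "tone")
  pri <- pri[order(tones != "reinforcing")]
  chunk2_factors <- setdiff(tailorable_factors(), pri)
  render <- function(fs) {
    stats::setNames(vapply(fs, function(f) {
      personalize(variants[[f]]$template, name, age)
    }, character(1)), fs)
  }
  bundle <- structure(
    list(name = name, age = as.integer(age), stage = as.character(stage),
         chunk1 = render(pri), chunk2 = render(chunk2_factors),
         override = override),
    class = "tailored_bundle")
  stopifnot(!any(grepl("[][]", c(bundle$chunk1, bundle$chunk2)))) # totality
  bundle
}

#' @export
format.tailored_bundle <- function(x, ...) {
  if (!is.null(x$override)) return(x$override)
  paste(
    "Your Information (Part 1)",
    paste(x$chunk1, collapse = "\n\n"),
    "Your Information (Part 2)",
    paste(x$chunk2, collapse = "\n\n"),
    sep = "\n\n")
}

#' @export
print.tailored_bundle <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' Generic (non-tailored) information statements
#'
#' The fixed statement sequence shown to non-tailored intervention groups.
#' Identical for every recipient; contains no personalization tokens.
#'
#' @return A `generic_bundle`: character vector of statements.
#' @export
generic_bundle <- function() {
  structure(c(
    "People can have colon polyps or cancer and not even know it. Colon polyps are common in people over 50, even in those with no family history.",
    "Finding colon cancer early and removing colon polyps when they are small can prevent cancer.",
    "The risk for these conditions increases with age; that's why regular screening from the age of 50 onwards is so important.",
    "Colon cancer screening is very effective—that's why the Australian Cancer Council recommends yearly screening for people over 50 who are of average risk.",
    "The medical profession recognizes that such screening is effective, and supports the Australian Cancer Council recommendation for yearly screening.",
    "Colorectal cancer screening is easy to do. The kit is designed to be quickly and easily used in the privacy of your home at your own convenience.",
    "Some people may think that doing the test might be unhygienic or embarrassing, but this needn't be so. Recognizing that there is nothing wrong with testing feces for cancer and using the kit could save lives."
  ), class = "generic_bundle")
}
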