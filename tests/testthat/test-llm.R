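# Prompt generation, example selection, response parsing, backend harness.

test_that("candidate pool excludes description concepts, then rare ones", {
  pool <- eligible_concepts(.ont)
  expect_length(pool, 98L)  # 101 binary minus the 3 description concepts
  expect_false(any(startsWith(pool, "desc.")))

  labels <- list(c("side.right", "loc.elbow"), c("side.right"),
                 c("loc.elbow"), character(0))
  keep <- eligible_concepts(.ont, labels)
  expect_setequal(keep, c("side.right", "loc.elbow"))  # >= 2 positives each
  labels2 <- list(c("side.right"), character(0))
  expect_false("side.right" %in% eligible_concepts(.ont, labels2))
  expect_length(eligible_concepts(.ont, list()), 0L)
})

test_that("few-shot prompts have 4 example exchanges and a fresh query", {
  ex <- list(positive = c("p one", "p two"), negative = c("n one", "n two"))
  p <- build_prompt("Active Range of Motion", "few_shot", ex, "query text")
  expect_equal(nrow(p$turns), 10L)  # system + 4 exchanges x 2 + query
  expect_equal(p$turns$role[1L], "System")
  expect_equal(p$turns$role[nrow(p$turns)], "User")
  expect_equal(sum(p$turns$text == "Yes."), 2L)
  expect_equal(sum(p$turns$text == "No."), 2L)
  # alternation: positive/negative/positive/negative
  model_turns <- p$turns$text[p$turns$role == "Model"]
  expect_equal(model_turns, c("Yes.", "No.", "Yes.", "No."))

  z <- build_prompt("Active Range of Motion", "zero_shot",
                    query_text = "query text")
  expect_equal(nrow(z$turns), 2L)
  expect_equal(z$turns$role, c("System", "User"))

  expect_error(build_prompt("X", "few_shot",
                            list(positive = "only one", negative = ex$negative),
                            "q"),
               "exactly 2")
  # purity: same inputs, same bytes
  expect_identical(format_prompt(p),
                   format_prompt(build_prompt("Active Range of Motion",
                                              "few_shot", ex, "query text")))
})

test_that("example selection is seed-deterministic and label-faithful", {
  texts <- c(paste("arom pos", 1:50), paste("neg text", 1:50))
  labels <- c(rep(list("motion.active_rom"), 50L),
              rep(list(character(0)), 50L))
  ex <- select_examples(texts, labels, "motion.active_rom", seed = 4L)
  expect_length(ex$positive, 2L)
  expect_length(ex$negative, 2L)
  expect_true(all(grepl("pos", ex$positive)))
  expect_true(all(grepl("neg", ex$negative)))
  expect_identical(ex, select_examples(texts, labels, "motion.active_rom",
                                       seed = 4L))
  # with 50 positives, two seeds almost surely differ
  ex2 <- select_examples(texts, labels, "motion.active_rom", seed = 5L)
  expect_false(identical(ex$positive, ex2$positive) &&
                 identical(ex$negative, ex2$negative))

  # exactly 2 positives: forced choice under any seed
  texts3 <- c("arom a", "arom b", "x", "y", "z")
  labels3 <- c(rep(list("motion.active_rom"), 2L), rep(list(character(0)), 3L))
  for (s in 1:3) {
    exf <- select_examples(texts3, labels3, "motion.active_rom", seed = s)
    expect_setequal(exf$positive, c("arom a", "arom b"))
  }
  expect_error(select_examples("arom a", list("motion.active_rom"),
                               "motion.active_rom"),
               "ineligible")
})

test_that("responses parse on their leading yes/no token only", {
  expect_true(parse_response("Yes."))
  expect_false(parse_response("No."))
  expect_true(parse_response("  yes, it does"))
  expect_false(parse_response("NO mention found"))
  expect_true(is.na(parse_response("It depends")))
  expect_true(is.na(parse_response("maybe yes")))
  expect_true(is.na(parse_response(NA_character_)))
})

test_that("backend harness is lossless: every item answered or errored", {
  kw <- list("Active Range of Motion" = c("AROM", "active ROM"))
  backend <- mock_keyword_backend(kw)
  queries <- c("1: AROM right elbow", "2: PROM left knee", "1: AROM right elbow")
  prompts <- lapply(queries, function(q)
    build_prompt("Active Range of Motion", "zero_shot", query_text = q))
  res <- classify_with_backend(prompts, backend)
  expect_equal(res$prediction, c(1L, 0L, 1L))
  # duplicate queries get duplicate, consistent predictions
  expect_equal(res$prediction[1L], res$prediction[3L])

  # a backend that always fails: all items errored, none dropped
  boom <- function(turns) stop("backend down")
  res2 <- classify_with_backend(prompts, boom, retries = 2L)
  expect_equal(nrow(res2), 3L)
  expect_true(all(!is.na(res2$error)))
  expect_true(all(res2$prediction == 0L))

  # indeterminate replies score negative but are flagged
  shrug <- function(turns) "It depends on the context"
  res3 <- classify_with_backend(prompts[1L], shrug)
  expect_equal(res3$prediction, 0L)
  expect_true(res3$indeterminate)
})

test_that("an oracle mock reproduces gold labels end to end", {
  corpus <- generate_corpus(6, default_generator_config(), .ont, seed = 21L)
  texts <- flat_texts(corpus)
  labels <- unname(flat_labels(corpus))
  concept <- "side.right"
  name <- .ont$concepts$name[.ont$concepts$id == concept]
  gold <- vapply(labels, function(l) concept %in% l, logical(1))
  oracle <- function(turns) {
    q <- turns$text[nrow(turns)]
    if (gold[match(q, texts)]) "Yes." else "No."
  }
  prompts <- lapply(texts, function(q)
    build_prompt(name, "zero_shot", query_text = q))
  res <- classify_with_backend(prompts, oracle)
  expect_equal(res$prediction, as.integer(gold))
})
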