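# Sequence/span/numeric metrics, Fleiss kappa, train/test split.

test_that("sequence metrics match the direct confusion-matrix formulas", {
  pred <- list(s1 = "a", s2 = "a", s3 = character(0))
  gold <- list(s1 = "a", s2 = character(0), s3 = "a")
  ev <- sequence_metrics(pred, gold, min_support = 1L)
  row <- ev$per_concept[ev$per_concept$concept_id == "a", ]
  expect_equal(c(row$tp, row$fp, row$fn), c(1L, 1L, 1L))
  expect_equal(c(row$precision, row$recall, row$f1), c(0.5, 0.5, 0.5))

  # pred == gold => F1 1.0 on every supported concept
  ev2 <- sequence_metrics(gold, gold, min_support = 1L)
  expect_true(all(ev2$per_concept$f1 == 1))

  # id mismatch errors, listing orphans
  expect_error(sequence_metrics(pred, gold[1:2]), "only in pred.*s3")

  # concepts absent from both sides are excluded entirely
  ev3 <- sequence_metrics(pred, gold, concepts = c("a", "ghost"),
                          min_support = 1L)
  expect_false("ghost" %in% ev3$per_concept$concept_id)
})

test_that("swapping pred and gold swaps P and R and preserves F1", {
  set.seed(41)
  concepts <- letters[1:5]
  ids <- paste0("s", 1:30)
  rand_labels <- function() {
    out <- lapply(ids, function(i) sample(concepts, sample(0:3, 1)))
    names(out) <- ids
    out
  }
  for (rep in 1:5) {
    pred <- rand_labels(); gold <- rand_labels()
    a <- sequence_metrics(pred, gold, concepts = concepts, min_support = 1L)
    b <- sequence_metrics(gold, pred, concepts = concepts, min_support = 1L)
    pa <- a$per_concept[order(a$per_concept$concept_id), ]
    pb <- b$per_concept[order(b$per_concept$concept_id), ]
    expect_equal(pa$precision, pb$recall)
    expect_equal(pa$recall, pb$precision)
    expect_equal(pa$f1, pb$f1)
  }
})

test_that("span metrics distinguish exact from overlap matching", {
  gold <- data.frame(sequence_id = "s1", concept_id = "a",
                     start = 0L, end = 5L, stringsAsFactors = FALSE)
  same <- gold
  off1 <- transform(gold, start = 1L, end = 6L)
  far <- transform(gold, start = 10L, end = 15L)

  both <- span_metrics(same, gold, min_support = 1L)
  expect_equal(both$exact$per_concept$f1, 1)
  expect_equal(both$overlap$per_concept$f1, 1)

  near <- span_metrics(off1, gold, min_support = 1L)
  expect_equal(near$overlap$per_concept$tp, 1L)     # intersecting spans
  expect_equal(near$exact$per_concept$tp, 0L)       # offsets differ
  expect_equal(near$exact$per_concept$fp, 1L)
  expect_equal(near$exact$per_concept$fn, 1L)

  apart <- span_metrics(far, gold, min_support = 1L)
  expect_equal(apart$exact$per_concept$tp, 0L)
  expect_equal(apart$overlap$per_concept$tp, 0L)

  expect_error(span_metrics(transform(gold, end = -1L), gold),
               "invalid spans")
})

test_that("numeric matching is exact-integer by kind after normalization", {
  gold <- data.frame(sequence_id = c("s1", "s1"), kind = c("reps", "duration_seconds"),
                     value = c(10L, 60L), stringsAsFactors = FALSE)
  pred_good <- gold
  nm <- numeric_metrics(pred_good, gold)
  expect_equal(nm$f1[nm$kind == "reps"], 1)
  # one minute expressed in seconds matches after normalization
  expect_equal(nm$f1[nm$kind == "duration_seconds"], 1)

  # kind mismatch: sets=2 against reps=2 is FP + FN
  pred_kind <- data.frame(sequence_id = "s1", kind = "sets", value = 2L,
                          stringsAsFactors = FALSE)
  gold_kind <- data.frame(sequence_id = "s1", kind = "reps", value = 2L,
                          stringsAsFactors = FALSE)
  nm2 <- numeric_metrics(pred_kind, gold_kind)
  expect_equal(nm2$fp[nm2$kind == "sets"], 1L)
  expect_equal(nm2$fn[nm2$kind == "reps"], 1L)

  # multiset matching: a duplicate gold value needs two predictions
  gold_dup <- data.frame(sequence_id = "s1", kind = "reps",
                         value = c(10L, 10L), stringsAsFactors = FALSE)
  nm3 <- numeric_metrics(pred_good[1, ], gold_dup)
  expect_equal(nm3$tp[nm3$kind == "reps"], 1L)
  expect_equal(nm3$fn[nm3$kind == "reps"], 1L)
})

test_that("Fleiss kappa behaves at its anchor points", {
  # perfect agreement across two used categories
  perfect <- rbind(matrix(c(3L, 0L), 5, 2, byrow = TRUE),
                   matrix(c(0L, 3L), 5, 2, byrow = TRUE))
  expect_equal(as.numeric(fleiss_kappa(perfect)), 1)

  # a hand-computed worked instance: 4 items, 3 raters, 2 categories
  # rows (3,0),(2,1),(1,2),(0,3): P_bar = 2/3, P_e = 1/2, kappa = 1/3
  worked <- matrix(c(3L, 0L, 2L, 1L, 1L, 2L, 0L, 3L), 4, 2, byrow = TRUE)
  expect_equal(as.numeric(fleiss_kappa(worked)), 1 / 3)

  # permutation invariance over items
  shuffled <- worked[c(3, 1, 4, 2), ]
  expect_equal(as.numeric(fleiss_kappa(shuffled)),
               as.numeric(fleiss_kappa(worked)))

  # degenerate: one category used throughout => undefined, flagged
  degenerate <- matrix(c(3L, 0L), 6, 2, byrow = TRUE)
  k <- fleiss_kappa(degenerate)
  expect_true(is.na(k))
  expect_match(attr(k, "reason"), "undefined")

  expect_error(fleiss_kappa(matrix(integer(0), 0, 2)), "at least one item")
  expect_error(fleiss_kappa(matrix(c(1L, 0L), 1, 2)), "at least 2 raters")
  expect_error(fleiss_kappa(matrix(c(3L, 0L, 2L, 0L), 2, 2, byrow = TRUE)),
               "same number of ratings")
})

test_that("stratified split partitions reproducibly with fallback", {
  enriched <- paste0("e", 1:150)
  random <- paste0("r", 1:150)
  sp <- split_train_test(enriched, random, seed = 7L)
  expect_length(sp$train, 250L)
  expect_length(sp$test, 50L)
  expect_length(intersect(sp$train, sp$test), 0L)
  expect_setequal(c(sp$train, sp$test), c(enriched, random))
  expect_identical(sp, split_train_test(enriched, random, seed = 7L))

  # strata of 100: proportional 5:1 fallback with a warning
  expect_warning(
    sp2 <- split_train_test(paste0("e", 1:100), paste0("r", 1:100), seed = 7L),
    "proportional fallback")
  expect_length(sp2$train, 166L)  # round(100 * 125/150) per stratum
  expect_length(sp2$test, 34L)
})
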