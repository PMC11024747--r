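# Scoring predictions against gold at sequence, span and numeric levels;
# Fleiss kappa for interannotator agreement; the stratified train/test
# split.

prf <- function(tp, fp, fn) {
  tp <- as.numeric(tp); fp <- as.numeric(fp); fn <- as.numeric(fn)
  p <- if (tp + fp > 0) tp / (tp + fp) else 0
  r <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (p + r > 0) 2 * p * r / (p + r) else 0
  c(precision = p, recall = r, f1 = f1)
}

#' Sequence-level per-concept precision/recall/F1
#'
#' Scores binary concept labels over sequences keyed by shared ids. Per
#' concept: TP when both prediction and gold carry the concept for a
#' sequence, FP/FN otherwise. Macro averages run over concepts with at
#' least `min_support` gold-positive sequences (sparse concepts are omitted,
#' as is conventional when most of a broad ontology is rarely attested);
#' concepts with zero gold and zero predicted positives are dropped
#' entirely.
#'
#' @param pred Named list: sequence id -> character vector of concept ids.
#' @param gold Named list in the same shape, same ids.
#' @param concepts Concept universe to score (default: union observed).
#' @param min_support Minimum gold positives for macro inclusion (default 10).
#' @return An object of class `rehab_eval`: `per_concept` data.frame and
#'   `macro` list (`precision`, `recall`, `f1`, `n_concepts`).
#' @export
sequence_metrics <- function(pred, gold, concepts = NULL, min_support = 10L) {
  orphans_p <- setdiff(names(pred), names(gold))
  orphans_g <- setdiff(names(gold), names(pred))
  if (length(orphans_p) || length(orphans_g)) {
    stop("sequence id mismatch; only in pred: [",
         paste(orphans_p, collapse = ", "), "], only in gold: [",
         paste(orphans_g, collapse = ", "), "]")
  }
  ids <- names(gold)
  if (is.null(concepts)) {
    concepts <- sort(unique(c(unlist(pred), unlist(gold))))
  }
  rows <- lapply(concepts, function(cid) {
    in_pred <- vapply(pred[ids], function(l) cid %in% l, logical(1))
    in_gold <- vapply(gold[ids], function(l) cid %in% l, logical(1))
    tp <- sum(in_pred & in_gold)
    fp <- sum(in_pred & !in_gold)
    fn <- sum(!in_pred & in_gold)
    tn <- sum(!in_pred & !in_gold)
    s <- prf(tp, fp, fn)
    data.frame(concept_id = cid, tp = tp, fp = fp, fn = fn, tn = tn,
               support = tp + fn, precision = s["precision"],
               recall = s["recall"], f1 = s["f1"], stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, rows)
  rownames(per) <- NULL
  per <- per[per$support > 0L | per$tp + per$fp > 0L, , drop = FALSE]
  per$in_macro <- per$support >= min_support
  macro_rows <- per[per$in_macro, , drop = FALSE]
  macro <- list(
    precision = if (nrow(macro_rows)) mean(macro_rows$precision) else NA_real_,
    recall = if (nrow(macro_rows)) mean(macro_rows$recall) else NA_real_,
    f1 = if (nrow(macro_rows)) mean(macro_rows$f1) else NA_real_,
    n_concepts = nrow(macro_rows)
  )
  structure(list(per_concept = per, macro = macro, level = "sequence",
                 min_support = min_support),
            class = "rehab_eval")
}

#' @export
print.rehab_eval <- function(x, ...) {
  cat("Evaluation report (", x$level, " level): ", nrow(x$per_concept),
      " concepts scored\n", sep = "")
  cat(sprintf("  macro over %d concepts (support >= %d): P=%.3f R=%.3f F1=%.3f\n",
              x$macro$n_concepts, x$min_support,
              x$macro$precision, x$macro$recall, x$macro$f1))
  invisible(x)
}

# Greedy one-to-one span matching for one (sequence, concept) pair.
match_spans <- function(p, g, mode) {
  used <- rep(FALSE, nrow(g))
  tp <- 0L
  for (i in seq_len(nrow(p))) {
    for (j in seq_len(nrow(g))) {
      if (used[j]) next
      hit <- if (mode == "exact") {
        p$start[i] == g$start[j] && p$end[i] == g$end[j]
      } else {
        p$start[i] < g$end[j] && g$start[j] < p$end[i]
      }
      if (hit) { used[j] <- TRUE; tp <- tp + 1L; break }
    }
  }
  c(tp = tp, fp = nrow(p) - tp, fn = nrow(g) - tp)
}

#' Span-level (NER) metrics under exact and overlap matching
#'
#' A predicted mention is a true positive when a gold mention of the same
#' concept in the same sequence corresponds to it under the match mode:
#' identical offsets (`exact`) or intersecting spans (`overlap`). Both modes
#' are reported, since off-by-a-character span disagreements are a known
#' source of NER/sequence score divergence.
#'
#' @param pred,gold Data.frames with columns `sequence_id`, `concept_id`,
#'   `start`, `end`.
#' @param min_support Macro-average support floor (default 10).
#' @return A list with `rehab_eval` elements `exact` and `overlap`.
#' @export
span_metrics <- function(pred, gold, min_support = 10L) {
  need <- c("sequence_id", "concept_id", "start", "end")
  stopifnot(all(need %in% names(pred)), all(need %in% names(gold)))
  if (any(pred$end < pred$start) || any(gold$end < gold$start)) {
    stop("invalid spans: end precedes start")
  }
  concepts <- sort(unique(c(pred$concept_id, gold$concept_id)))
  out <- lapply(c(exact = "exact", overlap = "overlap"), function(mode) {
    rows <- lapply(concepts, function(cid) {
      pc <- pred[pred$concept_id == cid, , drop = FALSE]
      gc <- gold[gold$concept_id == cid, , drop = FALSE]
      counts <- c(tp = 0L, fp = 0L, fn = 0L)
      for (sid in unique(c(pc$sequence_id, gc$sequence_id))) {
        counts <- counts + match_spans(
          pc[pc$sequence_id == sid, , drop = FALSE],
          gc[gc$sequence_id == sid, , drop = FALSE], mode)
      }
      s <- prf(counts["tp"], counts["fp"], counts["fn"])
      data.frame(concept_id = cid, tp = counts[["tp"]], fp = counts[["fp"]],
                 fn = counts[["fn"]], tn = NA_integer_,
                 support = counts[["tp"]] + counts[["fn"]],
                 precision = s["precision"], recall = s["recall"],
                 f1 = s["f1"], stringsAsFactors = FALSE)
    })
    per <- do.call(rbind, rows)
    rownames(per) <- NULL
    per$in_macro <- per$support >= min_support
    macro_rows <- per[per$in_macro, , drop = FALSE]
    structure(list(
      per_concept = per,
      macro = list(
        precision = if (nrow(macro_rows)) mean(macro_rows$precision) else NA_real_,
        recall = if (nrow(macro_rows)) mean(macro_rows$recall) else NA_real_,
        f1 = if (nrow(macro_rows)) mean(macro_rows$f1) else NA_real_,
        n_concepts = nrow(macro_rows)),
      level = paste0("span/", mode), min_support = min_support),
      class = "rehab_eval")
  })
  out
}

#' Numeric duration/sets/reps metrics
#'
#' Since the numeric categories have no enumerated concepts, the value in
#' each finding is the unit of comparison: a prediction is a true positive
#' exactly when a gold finding of the same kind and the same integer value
#' (durations unit-normalized to seconds) exists in the same sequence,
#' under multiset matching. No numeric tolerance is applied.
#'
#' @param pred,gold Data.frames with columns `sequence_id`, `kind`, `value`.
#' @return A data.frame with one row per kind: counts and P/R/F1.
#' @export
numeric_metrics <- function(pred, gold) {
  need <- c("sequence_id", "kind", "value")
  stopifnot(all(need %in% names(pred)), all(need %in% names(gold)))
  kinds <- c("duration_seconds", "sets", "reps")
  rows <- lapply(kinds, function(k) {
    pk <- pred[pred$kind == k, , drop = FALSE]
    gk <- gold[gold$kind == k, , drop = FALSE]
    tp <- 0L
    for (sid in unique(c(pk$sequence_id, gk$sequence_id))) {
      pv <- pk$value[pk$sequence_id == sid]
      gv <- gk$value[gk$sequence_id == sid]
      for (v in pv) {
        hit <- match(v, gv)
        if (!is.na(hit)) { gv <- gv[-hit]; tp <- tp + 1L }
      }
    }
    fp <- nrow(pk) - tp
    fn <- nrow(gk) - tp
    s <- prf(tp, fp, fn)
    data.frame(kind = k, tp = tp, fp = fp, fn = fn,
               precision = s["precision"], recall = s["recall"], f1 = s["f1"],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Fleiss kappa for multi-rater categorical agreement
#'
#' Standard chance-corrected agreement for `m` raters assigning one of `k`
#' categories to each of `N` items. `matrix[i, j]` counts raters assigning
#' category `j` to item `i`; each row must sum to the same `m >= 2`. When
#' every rating falls in a single category the chance agreement is 1 and
#' kappa is undefined: `NA` is returned with an explanatory attribute
#' rather than a misleading number.
#'
#' @param ratings An items-by-categories integer matrix of rating counts.
#' @return Kappa (numeric scalar), with attributes `P_bar` (mean observed
#'   agreement) and `P_e` (expected chance agreement); `NA` when undefined.
#' @export
fleiss_kappa <- function(ratings) {
  ratings <- as.matrix(ratings)
  if (nrow(ratings) < 1L) stop("need at least one item")
  m <- sum(ratings[1L, ])
  if (m < 2L) stop("need at least 2 raters")
  if (!all(rowSums(ratings) == m)) {
    stop("every item must have the same number of ratings")
  }
  N <- nrow(ratings)
  p_j <- colSums(ratings) / (N * m)
  P_i <- (rowSums(ratings^2) - m) / (m * (m - 1))
  P_bar <- mean(P_i)
  P_e <- sum(p_j^2)
  if (isTRUE(all.equal(P_e, 1))) {
    out <- NA_real_
    attr(out, "reason") <- "all ratings in a single category; kappa undefined"
    attr(out, "P_bar") <- P_bar
    attr(out, "P_e") <- P_e
    return(out)
  }
  out <- (P_bar - P_e) / (1 - P_e)
  attr(out, "P_bar") <- P_bar
  attr(out, "P_e") <- P_e
  out
}

#' Stratified train/test split of annotated sections
#'
#' Takes `n_train_each` sections per stratum (enriched and random) for
#' training, the remainder for test; with 150 + 150 annotated sections and
#' the default 125 this yields 250 training and 50 test sections. Strata
#' smaller than `n_train_each` fall back to a proportional 5:1 split with a
#' warning.
#'
#' @param enriched,random Vectors of section ids (one per stratum).
#' @param n_train_each Training sections per stratum (default 125).
#' @param seed Integer RNG seed.
#' @return `list(train = ..., test = ...)` of section ids; a partition of
#'   the input.
#' @export
split_train_test <- function(enriched, random, n_train_each = 125L,
                             seed = 1L) {
  split_one <- function(ids) {
    n_train <- n_train_each
    if (length(ids) < n_train_each) {
      n_train <- round(length(ids) * n_train_each / 150)
      warning("stratum has ", length(ids), " < ", n_train_each,
              " sections; proportional fallback takes ", n_train,
              " for training")
    }
    pick <- sample(length(ids), n_train)
    list(train = ids[pick], test = ids[-pick])
  }
  with_seed(seed, {
    a <- split_one(enriched)
    b <- split_one(random)
    list(train = c(a$train, b$train), test = c(a$test, b$test))
  })
}
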