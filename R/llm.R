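# Zero-/few-shot yes-no extraction prompts for chat-model backends.
#
# For each concept, a prompt asks whether a given text segment from a
# medical record mentions that concept. Prompts are generated from a single
# template plus the concept's display name; the few-shot variant carries 2
# positive and 2 negative worked examples (alternating Yes./No. model
# turns), the zero-shot variant none. A deterministic mock backend makes the
# whole path testable offline.

.prompt_template <- paste0(
  "You are an assistant assigned to determine if a given text segment from ",
  "a medical record contains mentions of %s. You must answer yes or no.")

#' Concepts eligible for prompt-based extraction
#'
#' The candidate pool is every binary-classifiable concept except the three
#' exercise-description concepts (whether the procedure was performed
#' in-office, at home, or not at all) -- 98 under the shipped ontology; the
#' numeric duration/sets/reps categories carry no binary concepts in the
#' first place. Concepts with fewer than `min_positives` positive training
#' sequences are then dropped, since not enough few-shot examples could be
#' drawn for them.
#'
#' @param ontology A loaded `rehab_ontology`.
#' @param train_labels A list of character vectors of gold concept ids (one
#'   per training sequence); `NULL` returns the unfiltered candidate pool.
#' @param min_positives Frequency floor (default 2).
#' @return Character vector of eligible concept ids.
#' @export
eligible_concepts <- function(ontology, train_labels = NULL,
                              min_positives = 2L) {
  stopifnot(inherits(ontology, "rehab_ontology"))
  desc <- vapply(ontology$categories[["exercise_description"]]$concepts,
                 `[[`, character(1), "id")
  pool <- setdiff(ontology$binary_ids, desc)
  if (is.null(train_labels)) return(pool)
  if (length(train_labels) == 0L) return(character(0))
  counts <- vapply(pool, function(cid)
    sum(vapply(train_labels, function(l) cid %in% l, logical(1))), integer(1))
  pool[counts >= min_positives]
}

#' Build a zero- or few-shot yes/no prompt for one concept
#'
#' The system turn instantiates the template with the concept's display
#' name. In few-shot mode exactly 2 positive and 2 negative example texts
#' are interleaved positive/negative/positive/negative as User turns, each
#' answered by a Model turn of `"Yes."` or `"No."`; the final turn is the
#' unanswered query. Zero-shot mode has just the system turn and the query.
#' Prompt construction is pure: the same inputs always yield the same byte
#' sequence.
#'
#' @param concept_name Display name, e.g. `"Active Range of Motion"`.
#' @param mode `"few_shot"` or `"zero_shot"`.
#' @param examples For few-shot: `list(positive = c(a, b), negative = c(c, d))`.
#' @param query_text The text segment to classify.
#' @return An object of class `rehab_prompt` with a `turns` data.frame
#'   (`role` in System/User/Model, `text`).
#' @export
build_prompt <- function(concept_name, mode = c("few_shot", "zero_shot"),
                         examples = NULL, query_text) {
  mode <- match.arg(mode)
  stopifnot(is.character(concept_name), length(concept_name) == 1L,
            is.character(query_text), length(query_text) == 1L)
  system_text <- sprintf(.prompt_template, concept_name)
  turns <- data.frame(role = "System", text = system_text,
                      stringsAsFactors = FALSE)
  if (mode == "few_shot") {
    if (is.null(examples) || length(examples$positive) != 2L ||
        length(examples$negative) != 2L) {
      stop("few-shot mode requires exactly 2 positive and 2 negative examples")
    }
    ex <- data.frame(
      role = rep(c("User", "Model"), 4L),
      text = c(examples$positive[1L], "Yes.",
               examples$negative[1L], "No.",
               examples$positive[2L], "Yes.",
               examples$negative[2L], "No."),
      stringsAsFactors = FALSE)
    turns <- rbind(turns, ex)
  }
  turns <- rbind(turns, data.frame(role = "User", text = query_text,
                                   stringsAsFactors = FALSE))
  structure(list(concept_name = concept_name, mode = mode, turns = turns),
            class = "rehab_prompt")
}

#' Render a prompt as the printed dialogue
#'
#' @param prompt A `rehab_prompt`.
#' @return A single string, turns joined as `"Role: text"` paragraphs.
#' @export
format_prompt <- function(prompt) {
  stopifnot(inherits(prompt, "rehab_prompt"))
  paste(paste0(prompt$turns$role, ": ", prompt$turns$text), collapse = "\n\n")
}

#' @export
print.rehab_prompt <- function(x, ...) {
  cat(format_prompt(x), "\n")
  invisible(x)
}

#' Select few-shot examples for one concept
#'
#' Positives come from training sequences whose gold labels contain the
#' concept, negatives from the rest; 2 of each, uniformly at random and
#' reproducibly under `seed`.
#'
#' @param train_texts Training sequence texts.
#' @param train_labels Matching list of gold concept-id vectors.
#' @param concept_id Concept to sample for.
#' @param seed Integer RNG seed.
#' @return `list(positive = c(...), negative = c(...))`.
#' @export
select_examples <- function(train_texts, train_labels, concept_id, seed = 1L) {
  stopifnot(length(train_texts) == length(train_labels))
  pos_idx <- which(vapply(train_labels, function(l) concept_id %in% l,
                          logical(1)))
  neg_idx <- setdiff(seq_along(train_labels), pos_idx)
  if (length(pos_idx) < 2L || length(neg_idx) < 2L) {
    stop("concept '", concept_id, "' is ineligible: ", length(pos_idx),
         " positive and ", length(neg_idx), " negative training sequences")
  }
  with_seed(seed, {
    list(positive = train_texts[sample(pos_idx, 2L)],
         negative = train_texts[sample(neg_idx, 2L)])
  })
}

#' Parse a backend reply into a yes/no prediction
#'
#' Case-insensitive leading "yes" is `TRUE`, leading "no" is `FALSE`;
#' anything else is indeterminate (`NA`) and is scored as a negative
#' prediction downstream, with the raw text kept for audit.
#'
#' @param text The backend's reply.
#' @return `TRUE`, `FALSE` or `NA`.
#' @export
parse_response <- function(text) {
  if (!is.character(text) || length(text) != 1L || is.na(text)) return(NA)
  if (grepl("^\\s*yes\\b", text, ignore.case = TRUE, perl = TRUE)) return(TRUE)
  if (grepl("^\\s*no\\b", text, ignore.case = TRUE, perl = TRUE)) return(FALSE)
  NA
}

#' Deterministic keyword mock backend
#'
#' Answers `"Yes."` when any of the concept's keywords occurs in the final
#' User turn, `"No."` otherwise. `keyword_table` maps concept display names
#' to character vectors of (case-insensitive, token-bounded) keywords. Used
#' for offline tests; the live path plugs in an HTTP chat adapter with the
#' same `function(turns) -> text` contract.
#'
#' @param keyword_table Named list: concept name -> keywords.
#' @return A backend function.
#' @export
mock_keyword_backend <- function(keyword_table) {
  force(keyword_table)
  function(turns) {
    system_text <- turns$text[turns$role == "System"][1L]
    concept <- sub(".*contains mentions of (.*)\\. You must.*", "\\1",
                   system_text)
    query <- turns$text[nrow(turns)]
    kws <- keyword_table[[concept]]
    hit <- any(vapply(kws, function(k)
      grepl(compile_lexicon_pattern(k), query, perl = TRUE), logical(1)))
    if (isTRUE(hit)) "Yes." else "No."
  }
}

#' Classify texts through a pluggable chat backend
#'
#' Sends each prompt to `backend(turns)`, retries transient failures, and
#' never drops an item silently: failures after `retries` attempts are
#' recorded per item and the run continues. Indeterminate replies are scored
#' as negative predictions.
#'
#' @param prompts A list of `rehab_prompt` objects.
#' @param backend A `function(turns) -> reply text`.
#' @param retries Attempts per prompt (default 3).
#' @return A data.frame: `concept_name`, `mode`, `query`, `raw`,
#'   `prediction` (0/1), `indeterminate`, `error`.
#' @export
classify_with_backend <- function(prompts, backend, retries = 3L) {
  rows <- lapply(prompts, function(p) {
    stopifnot(inherits(p, "rehab_prompt"))
    raw <- NA_character_
    err <- NA_character_
    for (attempt in seq_len(retries)) {
      res <- tryCatch(backend(p$turns), error = function(e) e)
      if (!inherits(res, "error")) { raw <- res; err <- NA_character_; break }
      err <- conditionMessage(res)
    }
    ans <- parse_response(raw)
    data.frame(
      concept_name = p$concept_name,
      mode = p$mode,
      query = p$turns$text[nrow(p$turns)],
      raw = raw,
      prediction = as.integer(isTRUE(ans)),
      indeterminate = is.na(ans) && is.na(err),
      error = err,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
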