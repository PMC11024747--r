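# Note filtering, therapeutic-procedures section extraction, enrichment
# scoring and enriched/random section sampling.

#' Keep the notes that come from therapy visits
#'
#' Physical-therapy visits are identified by their file names: a note is kept
#' exactly when its filename contains the literal substring `"THERAPY"`.
#' Matching is case-sensitive by default since note types are conventionally
#' upper-cased; `ignore_case = TRUE` relaxes this.
#'
#' @param notes A data.frame with columns `filename` and `text`.
#' @param ignore_case Match the substring case-insensitively.
#' @return The subset of `notes` whose filenames match.
#' @export
filter_therapy_notes <- function(notes, ignore_case = FALSE) {
  stopifnot(is.data.frame(notes), all(c("filename", "text") %in% names(notes)))
  if (nrow(notes) == 0L) return(notes)
  if (any(!nzchar(notes$filename))) stop("empty filename in note set")
  keep <- grepl("THERAPY", notes$filename, fixed = !ignore_case,
                ignore.case = ignore_case)
  notes[keep, , drop = FALSE]
}

#' Default header pattern for the therapeutic-procedures section
#'
#' Matches the first line mentioning THERAPY/THERAPEUTIC; the section body
#' then runs to the next all-caps header line or the end of the note. The
#' exact sectioning of real notes varies by facility, so the pattern is a
#' configurable default rather than a fixed rule.
#' @return A PCRE string.
#' @export
default_section_pattern <- function() {
  "(?im)^[^\\n]*THERAP(?:Y|EUTIC)[^\\n]*(?:\\n|$)"
}

# A line that looks like the start of another note section.
.next_header_pattern <- "(?m)^[A-Z][A-Z0-9 /&'-]{3,}:?[ \\t]*$"

#' Extract the therapeutic-procedures section from a note
#'
#' Returns the first section matching `pattern` together with its character
#' offsets into the (newline-normalized) note, or `NULL` when the note has
#' no such section. Empty sections are permitted: brief or copy-paste
#' truncated notes may carry a header with no body.
#'
#' @param note_text Full note text.
#' @param pattern Header pattern; see [default_section_pattern()].
#' @return A list with `text`, `start`, `end` (0-based, half-open offsets of
#'   the section body) and `header`, or `NULL`.
#' @export
extract_section <- function(note_text, pattern = default_section_pattern()) {
  stopifnot(is.character(note_text), length(note_text) == 1L)
  ok <- tryCatch({grepl(pattern, "", perl = TRUE); TRUE},
                 error = function(e) FALSE)
  if (!ok) stop("section pattern does not compile: ", pattern)
  text <- normalize_newlines(note_text)
  m <- regexpr(pattern, text, perl = TRUE)
  if (m == -1L) return(NULL)
  body_start <- as.integer(m) + attr(m, "match.length")  # 1-based next char
  rest <- substring(text, body_start)
  h <- regexpr(.next_header_pattern, rest, perl = TRUE)
  body_end <- if (h == -1L) nchar(text) else body_start + as.integer(h) - 2L
  list(
    text = substring(text, body_start, body_end),
    start = body_start - 1L,
    end = body_end,
    header = substring(text, m, m + attr(m, "match.length") - 1L)
  )
}

# Internal: compiled scoring keywords per scoring group. Scoring uses
# case-insensitive whole-token matching regardless of the tagging lexicon's
# case flags ("uncased" text model), so "extension" can never fire "tension".
scoring_keywords <- function(ontology) {
  groups <- list()
  for (cat in ontology$categories) {
    if (!cat$scoring) next
    pats <- if (length(cat$keywords) > 0L) {
      vapply(cat$keywords, function(k)
        compile_lexicon_pattern(k$pattern, regex = isTRUE(k$regex),
                                case_sensitive = FALSE), character(1))
    } else {
      unlist(lapply(cat$concepts, function(con)
        vapply(con$lexicon, function(e)
          compile_lexicon_pattern(e$pattern, regex = isTRUE(e$regex),
                                  case_sensitive = FALSE), character(1))),
        use.names = FALSE)
    }
    groups[[cat$score_group]] <- c(groups[[cat$score_group]], pats)
  }
  groups
}

#' Score a section by ontology-category coverage
#'
#' Counts the scoring categories (type of motion, side, location, plane,
#' duration, sets-and-reps, exercise purpose, exercise type, body position)
#' with at least one keyword present in the text. A section mentioning every
#' scoring category scores the maximum, 9 for the shipped ontology; sections
#' with no keywords score 0. The score is used to oversample
#' information-dense ("enriched") sections.
#'
#' @param section_text Section text (a `Section$text` or plain string).
#' @param ontology A loaded `rehab_ontology`.
#' @return Integer score between 0 and the number of scoring groups.
#' @export
enrichment_score <- function(section_text, ontology) {
  stopifnot(is.character(section_text), length(section_text) == 1L,
            inherits(ontology, "rehab_ontology"))
  groups <- scoring_keywords(ontology)
  hits <- vapply(groups, function(pats) {
    any(vapply(pats, function(p) grepl(p, section_text, perl = TRUE),
               logical(1)))
  }, logical(1))
  as.integer(sum(hits))
}

#' Sample enriched and random section sets
#'
#' The enriched set takes every section with the maximum score plus a
#' uniform sample of sections scoring one below, up to `n_enriched`. The
#' random set is a uniform sample over sections at least `min_chars` long,
#' disjoint from the enriched set. Sampling is without replacement and
#' reproducible under `seed`.
#'
#' @param sections A data.frame with at least columns `id`, `text`, `score`.
#' @param n_enriched,n_random Target set sizes (default 300 each).
#' @param min_chars Length floor for the random set (default 200 characters).
#' @param seed Integer RNG seed.
#' @param max_score The score that qualifies outright (default: the maximum
#'   attainable under the shipped ontology, 9).
#' @return A list with data.frames `enriched` and `random`.
#' @export
sample_sections <- function(sections, n_enriched = 300L, n_random = 300L,
                            min_chars = 200L, seed = 1L, max_score = 9L) {
  stopifnot(is.data.frame(sections),
            all(c("id", "text", "score") %in% names(sections)),
            n_enriched >= 0L, n_random >= 0L)
  with_seed(seed, {
    top <- sections[sections$score == max_score, , drop = FALSE]
    near <- sections[sections$score == max_score - 1L, , drop = FALSE]
    if (nrow(top) >= n_enriched) {
      enriched <- top[sample(nrow(top), n_enriched), , drop = FALSE]
    } else {
      need <- n_enriched - nrow(top)
      if (nrow(near) < need) {
        stop("cannot form enriched set: need ", need, " score-",
             max_score - 1L, " sections, have ", nrow(near))
      }
      pick <- sample(nrow(near), need)
      enriched <- rbind(top, near[pick, , drop = FALSE])
    }
    pool <- sections[nchar(sections$text) >= min_chars &
                       !(sections$id %in% enriched$id), , drop = FALSE]
    if (nrow(pool) < n_random) {
      stop("cannot form random set: need ", n_random,
           " eligible sections, have ", nrow(pool))
    }
    random <- pool[sample(nrow(pool), n_random), , drop = FALSE]
    rownames(enriched) <- rownames(random) <- NULL
    list(enriched = enriched, random = random)
  })
}
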