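# Rule-based extraction: section segmentation into enumerated exercise
# sequences, lexicon + context tagging of concept mentions, exercise-status
# resolution, numeric duration/sets/reps parsing, and projection of span
# labels onto sequence-level binary labels.

#' Path to the packaged refinement rules
#' @return File path of the shipped rules YAML.
#' @export
default_rules_path <- function() {
  system.file("extdata", "rules.yaml", package = "rehabext", mustWork = TRUE)
}

#' Compile the rule set for tagging and numeric parsing
#'
#' Combines the ontology lexicons with the refinement rules: context rules
#' for the ambiguous abbreviations ("L"/"R" adjacent to a body location,
#' "SL" followed by a limb or stance word), the minutes-versus-feet
#' apostrophe convention, status precedence, and the deidentification
#' placeholder pattern.
#'
#' @param ontology A loaded `rehab_ontology`.
#' @param rules_path Rules YAML; defaults to the packaged file.
#' @return An object of class `rehab_ruleset`.
#' @export
build_ruleset <- function(ontology, rules_path = default_rules_path()) {
  stopifnot(inherits(ontology, "rehab_ontology"))
  cfg <- yaml::read_yaml(rules_path)
  lex <- ontology_lexicon(ontology)

  loc_cat <- ontology$categories[["location_on_body"]]
  loc_words <- if (!is.null(loc_cat)) {
    unique(tolower(unlist(lapply(loc_cat$concepts, function(con)
      vapply(con$lexicon, `[[`, character(1), "pattern")), use.names = FALSE)))
  } else character(0)
  # Only single-token location words can follow a single-letter side marker.
  loc_words <- loc_words[!grepl("\\s", loc_words)]

  structure(list(
    ontology = ontology,
    lexicon = lex,
    version = cfg$version %||% "unversioned",
    single_letter_side = cfg$context_rules$single_letter_side,
    sl_rule = cfg$context_rules$sl_single_leg,
    location_words = loc_words,
    locomotion_words = tolower(unlist(cfg$numeric_rules$apostrophe_locomotion_words)),
    apostrophe_context_chars = cfg$numeric_rules$apostrophe_context_chars %||% 30L,
    status_precedence = unlist(cfg$status_rules$precedence) %||%
      c("desc.not_performed", "desc.hep", "desc.in_office"),
    placeholder_pattern = cfg$placeholders$pattern %||% "\\[[A-Z]+\\]"
  ), class = "rehab_ruleset")
}

#' @export
print.rehab_ruleset <- function(x, ...) {
  cat("Rehabilitation extraction rule set (version ", x$version, ")\n", sep = "")
  cat("  ", nrow(x$lexicon), " lexicon patterns over ",
      length(unique(x$lexicon$concept_id)), " concepts\n", sep = "")
  invisible(x)
}

# List-item markers: "N:" anywhere (run-on note style) and "N." / "N)" at
# line starts. Returns marker positions with the printed item number.
find_markers <- function(text) {
  inline <- pattern_matches(text, "(?<![A-Za-z0-9])(\\d{1,3})\\s*:")
  linestart <- pattern_matches(text, "(?m)^\\s*(\\d{1,3})\\s*[.)]")
  m <- rbind(inline, linestart)
  if (nrow(m) == 0L) return(m)
  m <- m[order(m$start), , drop = FALSE]
  m <- m[!duplicated(m$start), , drop = FALSE]
  m$label <- gsub("[^0-9]", "", m$text)
  m
}

#' Segment a section into enumerated exercise sequences
#'
#' One sequence per enumerated item with non-whitespace text after its
#' marker. Printed item numbers are kept verbatim (numbering gaps, as in
#' notes whose list skips an index, are preserved). Sequence spans tile the
#' section from the first marker to the end, so concatenating the spans plus
#' the pre-list text reconstructs the section.
#'
#' @param section_text The section text.
#' @return A data.frame with columns `index_label`, `text` (item text after
#'   the marker), `start`, `end` (0-based half-open span of the whole item,
#'   marker included) and `text_start` (offset of `text` within the section).
#' @export
segment <- function(section_text) {
  stopifnot(is.character(section_text), length(section_text) == 1L)
  empty <- data.frame(index_label = character(0), text = character(0),
                      start = integer(0), end = integer(0),
                      text_start = integer(0), stringsAsFactors = FALSE)
  if (!nzchar(section_text)) return(empty)
  text <- normalize_newlines(section_text)
  m <- find_markers(text)
  if (nrow(m) == 0L) return(empty)
  n <- nrow(m)
  item_start <- m$start
  item_end <- c(m$start[-1L], nchar(text))
  body_start <- m$end
  body <- substring(text, body_start + 1L, item_end)
  out <- data.frame(
    index_label = m$label,
    text = body,
    start = item_start,
    end = item_end,
    text_start = body_start,
    stringsAsFactors = FALSE
  )
  out[grepl("\\S", out$text), , drop = FALSE]
}

# Spans (0-based half-open) of deidentification placeholders; matches whose
# span intersects one are discarded -- placeholders are opaque tokens.
placeholder_spans <- function(text, ruleset) {
  pattern_matches(text, ruleset$placeholder_pattern)
}

overlaps_any <- function(start, end, spans) {
  if (nrow(spans) == 0L) return(rep(FALSE, length(start)))
  vapply(seq_along(start), function(i) {
    any(start[i] < spans$end & spans$start < end[i])
  }, logical(1))
}

#' Tag concept mentions in one exercise sequence
#'
#' Dictionary matching over every lexicon pattern plus the context rules.
#' A match strictly contained in a longer match of the same category is
#' pruned ("horizontal abduction" suppresses "horizontal" and "abduction";
#' "active ROM" suppresses the inner "ROM" readings), while cross-category
#' containment is genuine co-mention and survives ("UE strengthening" names
#' the exercise type, the upper-extremity location and the strength purpose
#' at once). Equal-span matches for different concepts are all kept (bare
#' "ROM" names both the motion type and the exercise type; "LUE" names a
#' side and a location). Nothing inside a deidentification placeholder ever
#' matches.
#'
#' @param sequence_text Text of one exercise sequence.
#' @param ruleset A compiled `rehab_ruleset`.
#' @return A data.frame of mentions: `concept_id`, `start`, `end` (0-based,
#'   half-open, within the sequence), `matched_text`.
#' @export
tag <- function(sequence_text, ruleset) {
  stopifnot(is.character(sequence_text), length(sequence_text) == 1L,
            inherits(ruleset, "rehab_ruleset"))
  empty <- data.frame(concept_id = character(0), start = integer(0),
                      end = integer(0), matched_text = character(0),
                      stringsAsFactors = FALSE)
  if (!nzchar(sequence_text)) return(empty)
  lex <- ruleset$lexicon
  ph <- placeholder_spans(sequence_text, ruleset)

  hits <- vector("list", nrow(lex))
  for (i in seq_len(nrow(lex))) {
    m <- pattern_matches(sequence_text, lex$compiled[i])
    if (nrow(m) > 0L) {
      m$concept_id <- lex$concept_id[i]
      m$category <- lex$category[i]
      hits[[i]] <- m
    }
  }
  hits <- c(Filter(Negate(is.null), hits),
            list(context_rule_matches(sequence_text, ruleset)))
  out <- do.call(rbind, hits)
  if (is.null(out) || nrow(out) == 0L) return(empty)
  out <- out[!overlaps_any(out$start, out$end, ph), , drop = FALSE]
  if (nrow(out) == 0L) return(empty)

  out <- prune_contained(out)
  out <- out[!duplicated(out[c("concept_id", "start", "end")]), , drop = FALSE]
  out <- out[order(out$start, out$end, out$concept_id), , drop = FALSE]
  rownames(out) <- NULL
  data.frame(concept_id = out$concept_id, start = out$start, end = out$end,
             matched_text = out$text, stringsAsFactors = FALSE)
}

# Containment pruning of matches within a compositional phrase. A match
# strictly inside a longer match is dropped when both name concepts of the
# same category ("lateral flexion" is one plane of motion, not three) and
# when a bare ROM reading sits inside a refined type-of-motion phrase
# ("active ROM" is not additionally the range-of-motion exercise type).
# Cross-category containment is genuine co-mention and survives: "UE
# strengthening" names the exercise type, the upper-extremity location and
# the strength purpose at once.
.rom_pair <- c("motion.rom", "extype.rom")

prune_contained <- function(m) {
  keep <- rep(TRUE, nrow(m))
  for (i in seq_len(nrow(m))) {
    container <- m$start <= m$start[i] & m$end >= m$end[i] &
      (m$end - m$start) > (m$end[i] - m$start[i])
    if (!any(container)) next
    same_cat <- container & m$category == m$category[i]
    rom_in_motion <- container & m$concept_id[i] %in% .rom_pair &
      m$category == "type_of_motion"
    if (any(same_cat | rom_in_motion)) keep[i] <- FALSE
  }
  m[keep, , drop = FALSE]
}

# Context rules for the single-letter and "SL" abbreviations. Returns
# matches in the same shape as pattern_matches plus concept_id.
context_rule_matches <- function(text, ruleset) {
  empty <- data.frame(start = integer(0), end = integer(0),
                      text = character(0), concept_id = character(0),
                      category = character(0), stringsAsFactors = FALSE)
  rows <- list()

  sls <- ruleset$single_letter_side
  if (isTRUE(sls$enabled)) {
    for (letter in names(sls$letters)) {
      # The "/" guard keeps the L of "B/L" from double-firing as left.
      pat <- paste0("(?<![A-Za-z0-9/])", letter,
                    "(?![A-Za-z0-9])(?=\\s+([A-Za-z]+))")
      m <- gregexpr(pat, text, perl = TRUE)[[1]]
      if (m[1] != -1L) {
        for (k in seq_along(m)) {
          after <- substring(text, m[k] + 1L)
          nxt <- regmatches(after, regexpr("^\\s+([A-Za-z]+)", after, perl = TRUE))
          word <- tolower(gsub("^\\s+", "", nxt))
          if (length(word) == 1L && word %in% ruleset$location_words) {
            rows[[length(rows) + 1L]] <- data.frame(
              start = as.integer(m[k]) - 1L, end = as.integer(m[k]),
              text = letter, concept_id = sls$letters[[letter]],
              category = "side_of_body", stringsAsFactors = FALSE)
          }
        }
      }
    }
  }

  slr <- ruleset$sl_rule
  if (isTRUE(slr$enabled)) {
    m <- gregexpr("(?<![A-Za-z0-9])SL(?![A-Za-z0-9])", text, perl = TRUE)[[1]]
    if (m[1] != -1L) {
      followers <- tolower(unlist(slr$followers))
      for (k in seq_along(m)) {
        after <- substring(text, m[k] + 2L)
        nxt <- regmatches(after, regexpr("^\\s+([A-Za-z]+)", after, perl = TRUE))
        word <- tolower(gsub("^\\s+", "", nxt))
        if (length(word) == 1L && word %in% followers) {
          rows[[length(rows) + 1L]] <- data.frame(
            start = as.integer(m[k]) - 1L, end = as.integer(m[k]) + 1L,
            text = "SL", concept_id = slr$concept,
            category = "side_of_body", stringsAsFactors = FALSE)
        }
      }
    }
  }

  if (length(rows) == 0L) empty else do.call(rbind, rows)
}

#' Resolve the exercise status of a sequence
#'
#' Precedence: a not-performed marker (held, deferred, declined ...)
#' outranks a home-exercise-program marker, which outranks the in-office
#' default. "Deferred to HEP" therefore resolves to not performed while both
#' description labels stay in the binary label set.
#'
#' @param mentions Mentions from [tag()].
#' @param ruleset A compiled `rehab_ruleset`.
#' @return One of `"desc.not_performed"`, `"desc.hep"`, `"desc.in_office"`.
#' @export
resolve_status <- function(mentions, ruleset) {
  for (s in ruleset$status_precedence) {
    if (s == "desc.in_office") next
    if (s %in% mentions$concept_id) return(s)
  }
  "desc.in_office"
}

# Mark characters of `mask` covered by rows of `m` as consumed.
consume <- function(mask, m) {
  for (i in seq_len(nrow(m))) {
    mask[(m$start[i] + 1L):m$end[i]] <- TRUE
  }
  mask
}

unconsumed <- function(mask, m) {
  if (nrow(m) == 0L) return(m)
  free <- vapply(seq_len(nrow(m)), function(i)
    !any(mask[(m$start[i] + 1L):m$end[i]]), logical(1))
  m[free, , drop = FALSE]
}

#' Parse numeric duration, sets and reps findings
#'
#' Recognized dosage notations: `"AxB"` (A sets of B reps), `"x N"` and
#' `"N x"` (reps), `"N rep(s)"`, `"N set(s)"`, explicit time units
#' (`"30 sec"`, `"2 min"`, minutes and hours converted to seconds), and the
#' apostrophe-minutes convention (`"x 1'"` is one minute). An apostrophe
#' quantity preceded by a locomotion word ("tandem walking: 25' x 2") is a
#' distance in feet: it is recognized and reported in the `distances`
#' attribute but never emitted as a duration. Each stage consumes its
#' matched characters so "2x10" can never additionally yield reps 2 or 10.
#'
#' @param sequence_text Text of one exercise sequence.
#' @param ruleset A compiled `rehab_ruleset`.
#' @return A data.frame of findings: `kind` (`duration_seconds`, `sets`,
#'   `reps`), `value` (non-negative integer, durations in seconds), `start`,
#'   `end`, `unit_normalized`; with attribute `distances` (a data.frame of
#'   recognized feet measurements).
#' @export
parse_numeric <- function(sequence_text, ruleset) {
  stopifnot(is.character(sequence_text), length(sequence_text) == 1L)
  empty <- data.frame(kind = character(0), value = integer(0),
                      start = integer(0), end = integer(0),
                      unit_normalized = logical(0), stringsAsFactors = FALSE)
  attr(empty, "distances") <- data.frame(value = integer(0), start = integer(0),
                                         end = integer(0))
  if (!nzchar(sequence_text)) return(empty)
  text <- sequence_text
  mask <- rep(FALSE, nchar(text))
  ph <- placeholder_spans(text, ruleset)
  if (nrow(ph) > 0L) mask <- consume(mask, ph)
  findings <- list()
  distances <- list()
  push <- function(m, kind, value, normalized) {
    findings[[length(findings) + 1L]] <<- data.frame(
      kind = kind, value = as.integer(value), start = m$start, end = m$end,
      unit_normalized = normalized, stringsAsFactors = FALSE)
  }

  # 1. Explicit time units.
  m <- pattern_matches(text,
    "(?i)(\\d+)\\s*(seconds?|secs?|minutes?|mins?|hours?|hrs?)(?![A-Za-z])")
  m <- unconsumed(mask, m)
  if (nrow(m) > 0L) {
    for (i in seq_len(nrow(m))) {
      num <- as.integer(gsub("[^0-9]", "", m$text[i]))
      unit <- tolower(gsub("[^a-z]", "", tolower(m$text[i])))
      mult <- if (startsWith(unit, "h")) 3600L else if (startsWith(unit, "m")) 60L else 1L
      push(m[i, ], "duration_seconds", num * mult, mult != 1L)
    }
    mask <- consume(mask, m)
  }

  # 2. Apostrophe quantities: minutes, unless locomotion context => feet.
  m <- pattern_matches(text, "(\\d+)\\s*'")
  m <- unconsumed(mask, m)
  if (nrow(m) > 0L) {
    win <- ruleset$apostrophe_context_chars
    for (i in seq_len(nrow(m))) {
      before <- substring(text, max(1L, m$start[i] - win + 1L), m$start[i])
      words <- tolower(unlist(strsplit(before, "[^A-Za-z]+")))
      num <- as.integer(gsub("[^0-9]", "", m$text[i]))
      if (any(words %in% ruleset$locomotion_words)) {
        distances[[length(distances) + 1L]] <- data.frame(
          value = num, start = m$start[i], end = m$end[i])
      } else {
        push(m[i, ], "duration_seconds", num * 60L, TRUE)
      }
    }
    mask <- consume(mask, m)
  }

  # 3. Sets x reps ("2x10"); the right operand must not itself start a
  #    duration or a longer number.
  m <- pattern_matches(text, "(\\d+)\\s*[xX]\\s*(\\d+)(?!['0-9])")
  m <- unconsumed(mask, m)
  if (nrow(m) > 0L) {
    for (i in seq_len(nrow(m))) {
      nums <- as.integer(regmatches(m$text[i],
                                    gregexpr("\\d+", m$text[i]))[[1]])
      sub <- m[i, ]
      push(sub, "sets", nums[1], FALSE)
      push(sub, "reps", nums[2], FALSE)
    }
    mask <- consume(mask, m)
  }

  # 4. Explicit rep / set counts.
  m <- pattern_matches(text, "(?i)(\\d+)\\s*reps?(?![A-Za-z])")
  m <- unconsumed(mask, m)
  if (nrow(m) > 0L) {
    for (i in seq_len(nrow(m)))
      push(m[i, ], "reps", as.integer(gsub("[^0-9]", "", m$text[i])), FALSE)
    mask <- consume(mask, m)
  }
  m <- pattern_matches(text, "(?i)(\\d+)\\s*sets?(?![A-Za-z])")
  m <- unconsumed(mask, m)
  if (nrow(m) > 0L) {
    for (i in seq_len(nrow(m)))
      push(m[i, ], "sets", as.integer(gsub("[^0-9]", "", m$text[i])), FALSE)
    mask <- consume(mask, m)
  }

  # 5. "x N" reps (not a duration: N must not carry an apostrophe).
  m <- pattern_matches(text, "(?<![A-Za-z0-9])[xX]\\s*(\\d+)(?!['0-9])")
  m <- unconsumed(mask, m)
  if (nrow(m) > 0L) {
    for (i in seq_len(nrow(m)))
      push(m[i, ], "reps", as.integer(gsub("[^0-9]", "", m$text[i])), FALSE)
    mask <- consume(mask, m)
  }

  # 6. "N x" reps ("20 x"); N must be a free-standing number.
  m <- pattern_matches(text, "(?<![A-Za-z0-9'])(\\d+)\\s*[xX](?![A-Za-z0-9])")
  m <- unconsumed(mask, m)
  if (nrow(m) > 0L) {
    for (i in seq_len(nrow(m)))
      push(m[i, ], "reps", as.integer(gsub("[^0-9]", "", m$text[i])), FALSE)
    mask <- consume(mask, m)
  }

  out <- if (length(findings)) do.call(rbind, findings) else empty
  out <- out[order(out$start, out$kind), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "distances") <- if (length(distances)) {
    do.call(rbind, distances)
  } else data.frame(value = integer(0), start = integer(0), end = integer(0))
  out
}

#' Project span-level findings onto sequence-level labels
#'
#' The binary label set is the union of the distinct mention concepts and
#' the status concept; numeric fields take the first finding of each kind in
#' span order (later collisions are recorded in the `collisions` attribute).
#' Idempotent and order-insensitive in its binary component.
#'
#' @param mentions Mentions from [tag()].
#' @param numerics Findings from [parse_numeric()].
#' @param status Status concept id from [resolve_status()].
#' @return A list: `binary` (sorted character vector of concept ids),
#'   `duration_seconds`, `sets`, `reps` (integer or `NA`), `status`.
#' @export
project <- function(mentions, numerics, status) {
  binary <- sort(unique(c(mentions$concept_id, status)))
  vals <- list(duration_seconds = NA_integer_, sets = NA_integer_,
               reps = NA_integer_)
  collisions <- list()
  if (nrow(numerics) > 0L) {
    numerics <- numerics[order(numerics$start), , drop = FALSE]
    for (kind in names(vals)) {
      rows <- numerics[numerics$kind == kind, , drop = FALSE]
      if (nrow(rows) > 0L) {
        vals[[kind]] <- rows$value[1L]
        if (length(unique(rows$value)) > 1L) {
          collisions[[kind]] <- rows$value
        }
      }
    }
  }
  out <- list(binary = binary, duration_seconds = vals$duration_seconds,
              sets = vals$sets, reps = vals$reps, status = status)
  if (length(collisions)) attr(out, "collisions") <- collisions
  out
}

#' Run the full rule-based extraction over one section
#'
#' Segments the section, then tags, status-resolves, numeric-parses and
#' projects each exercise sequence.
#'
#' @param section_text The section text.
#' @param ruleset A compiled `rehab_ruleset`.
#' @return A list of per-sequence records, each with `index_label`, `start`,
#'   `end`, `text`, `labels` (from [project()]) and `mentions`.
#' @export
extract_labels <- function(section_text, ruleset) {
  seqs <- segment(section_text)
  lapply(seq_len(nrow(seqs)), function(i) {
    s <- seqs[i, ]
    mentions <- tag(s$text, ruleset)
    numerics <- parse_numeric(s$text, ruleset)
    status <- resolve_status(mentions, ruleset)
    list(
      index_label = s$index_label,
      start = s$start, end = s$end, text = s$text,
      labels = project(mentions, numerics, status),
      mentions = mentions,
      numerics = numerics
    )
  })
}
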