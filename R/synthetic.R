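# Synthetic therapy-note generator with gold-standard labels.
#
# Emits numbered exercise-list sections in the documentation style of real
# therapy notes ("1: AROM right elbow flx/ext HEP", "5: foam Lunges: x 20
# B/L"), writing gold labels at emission time: every label is realized by a
# witnessing surface span, so gold is by construction rather than by
# re-parsing. The generator is the testbed standing in for a private
# hospital corpus; per-concept frequencies loosely follow the reported
# per-concept training counts, with a floor for concepts whose real
# prevalence is unknown.

#' Default generator configuration
#'
#' Slot presence probabilities, within-slot concept weights (loosely
#' calibrated to reported per-concept training-set counts, floored for
#' unreported concepts), exercise-status mix, numeric-notation mix,
#' abbreviation-variant rate, deidentification-placeholder rate, list-number
#' skip rate, and the ambiguity/typo channels (off by default).
#'
#' @return A named list; see source for every knob.
#' @export
default_generator_config <- function() {
  list(
    items_per_section = 4:12,
    slot_p = c(motion = 0.30, side = 0.45, location = 0.85, plane = 0.55,
               extype = 0.35, purpose = 0.15, position = 0.20,
               numeric = 0.70),
    plane_pair_p = 0.35,
    status_p = c(desc.in_office = 0.65, desc.hep = 0.10,
                 desc.not_performed = 0.25),
    deferred_to_hep_p = 0.15,
    numeric_mix = c(axb = 0.35, x_n = 0.30, n_x = 0.15, duration = 0.12,
                    n_rep = 0.08),
    variant_prob = 0.30,
    placeholder_rate = 0.05,
    skip_number_rate = 0.10,
    ambiguity_rate = 0,
    typo_rate = 0,
    concept_weights = list(
      type_of_motion = c(motion.active_rom = 103, motion.active_assisted_rom = 160,
                         motion.passive_rom = 121, motion.rom = 150),
      side_of_body = c(side.right = 548, side.left = 462, side.bilateral = 260,
                       side.unilateral = 30, side.contralateral = 30,
                       side.ipsilateral = 30),
      location_on_body = c(loc.upper_extremity = 285, loc.lower_extremity = 223,
                           loc.hip = 168, loc.knee = 108, loc.ankle = 55,
                           loc.shoulder = 224, loc.scapula = 72, loc.elbow = 147,
                           loc.forearm = 86, loc.wrist = 129, loc.hand = 243,
                           loc.thigh = 40, loc.foot = 40, loc.heel = 40,
                           loc.toe = 40, loc.thumb = 40, loc.head = 40,
                           loc.neck = 40, loc.chest = 40, loc.abdomen = 40,
                           loc.lower_back = 40),
      plane_of_motion = c(plane.flexion = 327, plane.extension = 266,
                          plane.abduction = 170, plane.forward = 148,
                          plane.lateral = 132, plane.backward = 92,
                          plane.supination = 82, plane.external_rotation = 74,
                          plane.anterior = 40),
      exercise_type = c(extype.le_strength = 447, extype.balance_vestibular = 351,
                        extype.gait_training = 310, extype.rom = 257,
                        extype.functional_mobility = 204,
                        extype.flexibility_mobility = 178,
                        extype.ue_strength = 138, extype.trunk_core_strength = 60,
                        extype.scapular_strength = 60, extype.cardio_aerobic = 60),
      exercise_purpose = c(purpose.simulated = 48),
      body_position = c(pos.weight_bearing = 255, pos.non_weight_bearing = 539)
    ),
    default_concept_weight = 40
  )
}

# Literal emission surfaces per concept, with the gold mention set each
# surface realizes. A surface shared by several concepts (bare "ROM", the
# LUE/RLE compounds) carries all of their ids. A multi-word surface that
# embeds a surface of a *different* category carries that concept too, at
# its sub-span ("UE strengthening" is the exercise type plus the
# upper-extremity location plus the strength purpose); same-category
# embeddings are compositional and carry nothing extra ("lateral flexion"
# is one plane), and a bare ROM reading inside a type-of-motion phrase is
# likewise absorbed. The table is computed once per ontology, so gold is a
# fixed property of each surface, not a re-parse of generated text.
emission_surfaces <- function(ontology) {
  lex <- ontology_lexicon(ontology)
  lex <- lex[!lex$regex, , drop = FALSE]
  key <- tolower(lex$pattern)
  surface_of <- split(lex$pattern, lex$concept_id)
  rom_pair <- c("motion.rom", "extype.rom")

  surfaces <- unique(lex$pattern[order(nchar(lex$pattern))])
  mention_table <- list()
  for (s in surfaces) {
    hits <- list()
    for (i in seq_len(nrow(lex))) {
      m <- pattern_matches(s, lex$compiled[i])
      if (nrow(m) > 0L) {
        m$concept_id <- lex$concept_id[i]
        m$category <- lex$category[i]
        hits[[length(hits) + 1L]] <- m
      }
    }
    m <- do.call(rbind, hits)
    keep <- rep(TRUE, nrow(m))
    for (i in seq_len(nrow(m))) {
      container <- m$start <= m$start[i] & m$end >= m$end[i] &
        (m$end - m$start) > (m$end[i] - m$start[i])
      if (!any(container)) next
      same_cat <- container & m$category == m$category[i]
      rom_in_motion <- container & m$concept_id[i] %in% rom_pair &
        m$category == "type_of_motion"
      if (any(same_cat | rom_in_motion)) keep[i] <- FALSE
    }
    m <- m[keep, , drop = FALSE]
    m <- m[!duplicated(m[c("concept_id", "start", "end")]), , drop = FALSE]
    mention_table[[tolower(s)]] <- data.frame(
      concept_id = m$concept_id, start = m$start, end = m$end,
      stringsAsFactors = FALSE)
  }
  list(
    by_concept = lapply(surface_of, unique),
    mention_table = mention_table
  )
}

# Gold mentions realized by one emitted surface, spans relative to it.
surface_mentions <- function(surf, text) {
  surf$mention_table[[tolower(text)]]
}

# Weighted concept pick within one category.
pick_concept <- function(cat, config, exclude = character(0)) {
  ids <- vapply(cat$concepts, `[[`, character(1), "id")
  ids <- setdiff(ids, c("desc.in_office", exclude))
  if (length(ids) == 0L) return(NULL)
  w <- config$concept_weights[[cat$name]]
  weights <- ifelse(ids %in% names(w), w[ids], config$default_concept_weight)
  sample(ids, 1L, prob = weights)
}

# Pick an emission surface for a concept: canonical (first lexicon entry)
# or, with variant_prob, one of its other listed surfaces.
pick_surface <- function(concept_id, surf, config) {
  s <- surf$by_concept[[concept_id]]
  if (is.null(s) || length(s) == 0L) return(NULL)
  if (length(s) > 1L && stats::runif(1) < config$variant_prob) {
    sample(s[-1L], 1L)
  } else {
    s[1L]
  }
}

mention_part <- function(text, surf) {
  list(text = text, mentions = surface_mentions(surf, text), numeric = NULL)
}
filler_part <- function(text) list(text = text, mentions = NULL, numeric = NULL)
numeric_part <- function(text, values) {
  list(text = text, mentions = NULL, numeric = values)
}
# A mention part with an explicitly intended reading (ambiguity channel).
intended_part <- function(text, concept_ids) {
  list(text = text,
       mentions = data.frame(concept_id = concept_ids, start = 0L,
                             end = nchar(text), stringsAsFactors = FALSE),
       numeric = NULL)
}

# One numeric dosage notation, drawn from the configured mix. Durations use
# the apostrophe-minutes idiom unless the sequence mentions locomotion, in
# which case an explicit "min" unit keeps minutes and feet apart.
draw_numeric <- function(config, locomotion) {
  mix <- config$numeric_mix / sum(config$numeric_mix)
  kind <- sample(names(mix), 1L, prob = mix)
  switch(kind,
    axb = {
      a <- sample(1:5, 1L); b <- sample(c(5L, 8L, 10L, 12L, 15L, 20L), 1L)
      numeric_part(paste0(a, "x", b), list(sets = a, reps = b))
    },
    x_n = {
      n <- sample(c(5L, 10L, 15L, 20L, 30L), 1L)
      numeric_part(paste("x", n), list(reps = n))
    },
    n_x = {
      n <- sample(c(5L, 10L, 15L, 20L, 30L), 1L)
      numeric_part(paste(n, "x"), list(reps = n))
    },
    duration = {
      n <- sample(1:15, 1L)
      if (locomotion) {
        numeric_part(paste(n, "min"), list(duration_seconds = n * 60L))
      } else {
        numeric_part(paste0("x ", n, "'"), list(duration_seconds = n * 60L))
      }
    },
    n_rep = {
      n <- sample(c(3L, 5L, 8L, 10L), 1L)
      numeric_part(paste(n, if (n == 1L) "rep" else "reps"), list(reps = n))
    })
}

# Ambiguity-channel injections: the context-dependent abbreviations that
# make real notes hard. Each carries its intended gold reading; some are
# recoverable by the context rules, some deliberately are not.
draw_ambiguity <- function(surf) {
  type <- sample(c("l_location", "l_bare", "sl_limb", "sl_posture",
                   "a_anterior", "distance"), 1L)
  switch(type,
    l_location = {
      word <- sample(c("knee", "ankle", "elbow", "wrist", "shoulder"), 1L)
      list(intended_part("L", "side.left"), mention_part(word, surf))
    },
    l_bare = list(intended_part("L", "side.left"), filler_part("cane")),
    sl_limb = {
      word <- sample(c("stance", "squat", "hop"), 1L)
      list(intended_part("SL", "side.unilateral"), filler_part(word))
    },
    sl_posture = list(filler_part("SL"), filler_part("rolling")),
    a_anterior = list(intended_part("A", "plane.anterior")),
    distance = {
      n <- sample(c(10L, 25L, 50L), 1L)
      list(mention_part("walking", surf), filler_part(paste0(n, "'")))
    })
}

apply_typos <- function(part, rate) {
  if (rate <= 0 || !is.null(part$mentions) || !is.null(part$numeric)) return(part)
  chars <- strsplit(part$text, "")[[1]]
  flip <- stats::runif(length(chars)) < rate & grepl("[a-z]", chars)
  chars[flip] <- sample(letters, sum(flip), replace = TRUE)
  part$text <- paste(chars, collapse = "")
  part
}

#' Generate one exercise sequence with gold labels
#'
#' Grammar-based emission: optional status marker, motion type, side,
#' location, plane(s), exercise type, purpose, body position and numeric
#' dosage slots, with surfaces drawn from the ontology lexicon. Gold labels
#' and mention spans are recorded as each surface is emitted. Assumes the
#' RNG state is already set (see [generate_corpus()]).
#'
#' @param config Generator configuration ([default_generator_config()]).
#' @param ontology A loaded `rehab_ontology`.
#' @param surf Cached [emission_surfaces()] table (recomputed when `NULL`).
#' @return A list: `text`, `labels` (binary/duration_seconds/sets/reps/
#'   status), `mentions` (data.frame of gold spans within `text`).
#' @export
generate_sequence <- function(config = default_generator_config(),
                              ontology, surf = NULL) {
  stopifnot(inherits(ontology, "rehab_ontology"))
  if (is.null(surf)) surf <- emission_surfaces(ontology)
  parts <- list()
  add <- function(p) parts[[length(parts) + 1L]] <<- p
  sp <- config$slot_p

  if (stats::runif(1) < config$placeholder_rate) {
    add(filler_part("[PERSONALNAME]"))
  }

  slot_cats <- c(motion = "type_of_motion", side = "side_of_body",
                 location = "location_on_body", extype = "exercise_type",
                 purpose = "exercise_purpose", position = "body_position")
  chosen <- list()
  for (slot in c("motion", "side", "location")) {
    if (stats::runif(1) < sp[[slot]]) {
      cid <- pick_concept(ontology$categories[[slot_cats[[slot]]]], config)
      s <- pick_surface(cid, surf, config)
      if (!is.null(s)) { chosen[[slot]] <- cid; add(mention_part(s, surf)) }
    }
  }
  if (stats::runif(1) < sp[["plane"]]) {
    cat <- ontology$categories[["plane_of_motion"]]
    p1 <- pick_concept(cat, config)
    s1 <- pick_surface(p1, surf, config)
    if (stats::runif(1) < config$plane_pair_p) {
      p2 <- pick_concept(cat, config, exclude = p1)
      s2 <- pick_surface(p2, surf, config)
      m1 <- surface_mentions(surf, s1)
      m2 <- surface_mentions(surf, s2)
      m2$start <- m2$start + nchar(s1) + 1L
      m2$end <- m2$end + nchar(s1) + 1L
      add(list(text = paste0(s1, "/", s2), mentions = rbind(m1, m2),
               numeric = NULL))
    } else {
      add(mention_part(s1, surf))
    }
  }
  for (slot in c("extype", "purpose", "position")) {
    if (stats::runif(1) < sp[[slot]]) {
      cid <- pick_concept(ontology$categories[[slot_cats[[slot]]]], config)
      s <- pick_surface(cid, surf, config)
      if (!is.null(s)) {
        # "for" keeps a location + purpose pair ("UE ... strength") from
        # accidentally spelling an exercise-type phrase.
        if (slot == "purpose") add(filler_part("for"))
        chosen[[slot]] <- cid
        add(mention_part(s, surf))
      }
    }
  }

  locomotion <- identical(chosen$extype, "extype.gait_training")
  if (stats::runif(1) < sp[["numeric"]]) add(draw_numeric(config, locomotion))

  status <- sample(names(config$status_p), 1L, prob = config$status_p)
  if (status == "desc.hep") {
    add(mention_part(pick_surface("desc.hep", surf, config), surf))
  } else if (status == "desc.not_performed") {
    if (stats::runif(1) < config$deferred_to_hep_p) {
      add(mention_part("deferred", surf))
      add(filler_part("to"))
      add(mention_part("HEP", surf))
    } else {
      s <- pick_surface("desc.not_performed", surf, config)
      if (stats::runif(1) < 0.5) s <- toupper(s)
      add(mention_part(s, surf))
    }
  }

  if (config$ambiguity_rate > 0 &&
      stats::runif(1) < config$ambiguity_rate) {
    for (p in draw_ambiguity(surf)) add(p)
  }

  if (config$typo_rate > 0) parts <- lapply(parts, apply_typos,
                                            rate = config$typo_rate)

  # Assemble text and gold spans.
  text <- ""
  mentions <- list()
  gold_binary <- character(0)
  numerics <- list(duration_seconds = NA_integer_, sets = NA_integer_,
                   reps = NA_integer_)
  for (p in parts) {
    offset <- if (nzchar(text)) nchar(text) + 1L else 0L
    text <- if (nzchar(text)) paste(text, p$text) else p$text
    if (!is.null(p$mentions) && nrow(p$mentions) > 0L) {
      m <- p$mentions
      m$start <- m$start + offset
      m$end <- m$end + offset
      m$matched_text <- substring(text, m$start + 1L, m$end)
      mentions[[length(mentions) + 1L]] <- m
      gold_binary <- c(gold_binary, m$concept_id)
    }
    if (!is.null(p$numeric)) {
      for (kind in names(p$numeric)) numerics[[kind]] <- p$numeric[[kind]]
    }
  }
  if (!nzchar(text)) { text <- "general conditioning"; }

  labels <- list(
    binary = sort(unique(c(gold_binary, status))),
    duration_seconds = numerics$duration_seconds,
    sets = numerics$sets,
    reps = numerics$reps,
    status = status
  )
  mentions <- if (length(mentions)) do.call(rbind, mentions) else
    data.frame(concept_id = character(0), start = integer(0),
               end = integer(0), matched_text = character(0),
               stringsAsFactors = FALSE)
  list(text = text, labels = labels, mentions = mentions)
}

#' Generate a gold-labeled synthetic corpus of note sections
#'
#' Sections are run-on numbered lists in the style of real therapeutic-
#' procedures sections, with occasional skipped list numbers and
#' deidentification placeholders. Deterministic under `seed`.
#'
#' @param n_sections Number of sections (>= 1).
#' @param config Generator configuration.
#' @param ontology A loaded `rehab_ontology`.
#' @param seed Integer RNG seed.
#' @return A list of gold sections, each `list(id, text, sequences)` where
#'   every sequence has `index_label`, `text`, `labels`, `mentions`.
#' @export
generate_corpus <- function(n_sections, config = default_generator_config(),
                            ontology = load_ontology(), seed = 1L) {
  if (!is.numeric(n_sections) || n_sections < 1L) {
    stop("n_sections must be >= 1")
  }
  surf <- emission_surfaces(ontology)
  with_seed(seed, {
    lapply(seq_len(n_sections), function(si) {
      n_items <- sample(config$items_per_section, 1L)
      skips <- stats::rbinom(n_items, 1L, config$skip_number_rate)
      numbers <- cumsum(1L + skips)
      text <- ""
      sequences <- vector("list", n_items)
      for (k in seq_len(n_items)) {
        s <- generate_sequence(config, ontology, surf)
        marker <- paste0(numbers[k], ": ")
        sequences[[k]] <- list(index_label = as.character(numbers[k]),
                               text = s$text, labels = s$labels,
                               mentions = s$mentions)
        text <- paste0(text, marker, s$text, " ")
      }
      list(id = paste0("synthetic_section_", si),
           text = sub(" $", "", text),
           sequences = sequences)
    })
  })
}

#' Export a gold corpus as standoff JSONL
#'
#' Same record shape as the rule-based extractor's output, so gold and
#' predictions diff directly.
#'
#' @param corpus From [generate_corpus()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
export_gold <- function(corpus, path) {
  records <- lapply(corpus, function(sec) {
    list(
      id = sec$id,
      text = sec$text,
      sequences = lapply(sec$sequences, function(sq) {
        list(
          index_label = sq$index_label,
          text = sq$text,
          labels = list(
            binary = as.list(sq$labels$binary),
            duration_seconds = if (is.na(sq$labels$duration_seconds)) NULL else
              sq$labels$duration_seconds,
            sets = if (is.na(sq$labels$sets)) NULL else sq$labels$sets,
            reps = if (is.na(sq$labels$reps)) NULL else sq$labels$reps,
            status = sq$labels$status
          ),
          mentions = if (nrow(sq$mentions) == 0L) list() else
            lapply(seq_len(nrow(sq$mentions)), function(i) {
              list(concept = sq$mentions$concept_id[i],
                   start = sq$mentions$start[i],
                   end = sq$mentions$end[i],
                   text = sq$mentions$matched_text[i])
            })
        )
      })
    )
  })
  write_jsonl(records, path)
}

#' Read a standoff JSONL gold corpus
#'
#' Inverse of [export_gold()].
#'
#' @param path A JSONL file.
#' @return A corpus in the shape produced by [generate_corpus()].
#' @export
read_gold <- function(path) {
  lapply(read_jsonl(path), function(rec) {
    list(
      id = rec$id,
      text = rec$text,
      sequences = lapply(rec$sequences, function(sq) {
        m <- if (length(sq$mentions) == 0L) {
          data.frame(concept_id = character(0), start = integer(0),
                     end = integer(0), matched_text = character(0),
                     stringsAsFactors = FALSE)
        } else {
          do.call(rbind, lapply(sq$mentions, function(mm) {
            data.frame(concept_id = mm$concept, start = mm$start,
                       end = mm$end, matched_text = mm$text,
                       stringsAsFactors = FALSE)
          }))
        }
        list(
          index_label = sq$index_label,
          text = sq$text,
          labels = list(
            binary = sort(unlist(sq$labels$binary) %||% character(0)),
            duration_seconds = sq$labels$duration_seconds %||% NA_integer_,
            sets = sq$labels$sets %||% NA_integer_,
            reps = sq$labels$reps %||% NA_integer_,
            status = sq$labels$status
          ),
          mentions = m
        )
      })
    )
  })
}
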