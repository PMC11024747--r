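# Rule-based extraction: segmentation, tagging, status, numerics,
# projection.

test_that("segmentation finds enumerated items and preserves gaps", {
  s1 <- segment(note_example_1)
  expect_equal(nrow(s1), 5L)
  expect_equal(s1$index_label, as.character(1:5))

  s2 <- segment(note_example_2)
  expect_equal(nrow(s2), 10L)
  expect_equal(s2$index_label, c("1", "2", "3", "4", "5", "6", "7",
                                 "9", "10", "11"))  # "8" absent in the note

  expect_equal(nrow(segment("")), 0L)
  expect_equal(nrow(segment("no markers in sight")), 0L)
  # items whose marker is followed only by whitespace are dropped
  expect_equal(segment("1:   2: real content")$index_label, "2")
})

test_that("segmentation spans partition the section", {
  for (text in c(note_example_1, note_example_2)) {
    s <- segment(text)
    prefix <- substring(text, 1L, s$start[1L])
    reconstructed <- paste0(prefix, paste(
      substring(text, s$start + 1L, s$end), collapse = ""))
    expect_identical(reconstructed, text)
    # no character belongs to two sequences
    expect_true(all(s$start[-1L] == s$end[-nrow(s)]))
  }
})

test_that("tagging recovers the concepts of the worked note lines", {
  m <- tag("AROM right elbow flx/ext HEP", .rules)
  expect_setequal(m$concept_id,
                  c("motion.active_rom", "side.right", "loc.elbow",
                    "plane.flexion", "plane.extension", "desc.hep"))
  # spans address the matched surface
  expect_equal(m$matched_text[m$concept_id == "motion.active_rom"], "AROM")
  expect_true(all(substring("AROM right elbow flx/ext HEP",
                            m$start + 1L, m$end) == m$matched_text))

  m2 <- tag("backward walking: 25' x 2", .rules)
  expect_true(all(c("plane.backward", "extype.gait_training") %in%
                    m2$concept_id))

  expect_equal(nrow(tag("", .rules)), 0L)
})

test_that("longer lexicon matches suppress contained ones, equal spans stay", {
  # "active ROM" absorbs the inner bare "ROM"
  m <- tag("active ROM shoulder", .rules)
  expect_setequal(m$concept_id, c("motion.active_rom", "loc.shoulder"))
  # equal-span multi-concept: bare ROM is both a motion and an exercise type
  m2 <- tag("shoulder ROM", .rules)
  expect_setequal(m2$concept_id, c("loc.shoulder", "motion.rom", "extype.rom"))
  # cross-category containment is genuine co-mention: "upper extremity
  # strength" names the exercise type, the location and the purpose
  m3 <- tag("upper extremity strength", .rules)
  expect_setequal(m3$concept_id,
                  c("extype.ue_strength", "loc.upper_extremity",
                    "purpose.strength"))
  # ... but same-category containment is compositional: one plane only
  m4 <- tag("horizontal abduction", .rules)
  expect_equal(m4$concept_id, "plane.horizontal_abduction")
})

test_that("context rules resolve single-letter and SL abbreviations", {
  expect_true("side.left" %in% tag("L knee stretch", .rules)$concept_id)
  expect_true("side.right" %in% tag("R ankle pumps", .rules)$concept_id)
  # "L5" is a machine level, not a side; bare L without a location is silent
  expect_false("side.left" %in% tag("Nustep: L5 x 10'", .rules)$concept_id)
  expect_false("side.left" %in% tag("L cane provided", .rules)$concept_id)
  # "B/L knee" is bilateral, and its L never double-fires as left
  mb <- tag("B/L knee", .rules)
  expect_true("side.bilateral" %in% mb$concept_id)
  expect_false("side.left" %in% mb$concept_id)
  # SL + stance word reads as single leg (unilateral)
  expect_true("side.unilateral" %in% tag("SL stance on foam", .rules)$concept_id)
  # SL + posture word is side-lying: not an ontology concept
  expect_false("side.unilateral" %in% tag("SL rolling", .rules)$concept_id)
})

test_that("deidentification placeholders are opaque to every rule", {
  m <- tag("[PERSONALNAME] maze - AROM LUE", .rules)
  expect_false(any(m$start < 14L))  # nothing fires inside the placeholder
  expect_true(all(c("motion.active_rom", "side.left",
                    "loc.upper_extremity") %in% m$concept_id))
  expect_equal(nrow(tag("[ADDRESS]", .rules)), 0L)
})

test_that("status resolution honors not-performed > HEP > in-office", {
  seqs <- list(
    list(text = "SL HS activation- x10 DEFERRED", want = "desc.not_performed"),
    list(text = "AROM right wrist flx/ext HEP", want = "desc.hep"),
    list(text = "foam balance (heel/toe rocking): x 30",
         want = "desc.in_office"),
    # deferred to HEP: both markers present, not-performed outranks
    list(text = "SLR- 2x10 deferred to HEP", want = "desc.not_performed"))
  for (s in seqs) {
    m <- tag(s$text, .rules)
    expect_equal(resolve_status(m, .rules), s$want, info = s$text)
  }
  # ... while both description labels survive in the binary set
  m <- tag("SLR- 2x10 deferred to HEP", .rules)
  lab <- project(m, parse_numeric("SLR- 2x10 deferred to HEP", .rules),
                 resolve_status(m, .rules))
  expect_true(all(c("desc.hep", "desc.not_performed") %in% lab$binary))
})

test_that("numeric parsing handles the dosage notations of real notes", {
  cases <- list(
    list(text = "Dips 4\" stair: 2x10", sets = 2L, reps = 10L),
    list(text = "foam balance: x 30", reps = 30L),
    list(text = "AROM Right wrist ext/flex - 20 x", reps = 20L),
    list(text = "tandem stance on foam x 1'", duration_seconds = 60L),
    list(text = "Nustep: L5 x 10'", duration_seconds = 600L),
    list(text = "AROM LUE - 3 rep", reps = 3L),
    list(text = "hold 30 sec", duration_seconds = 30L),
    list(text = "bike 5 minutes", duration_seconds = 300L),
    list(text = "3 sets of 12 reps", sets = 3L, reps = 12L))
  for (cs in cases) {
    f <- parse_numeric(cs$text, .rules)
    for (kind in c("sets", "reps", "duration_seconds")) {
      got <- f$value[f$kind == kind]
      if (is.null(cs[[kind]])) {
        expect_length(got, 0L)
      } else {
        expect_equal(got, cs[[kind]], info = paste(cs$text, kind))
      }
    }
    # spans address the parsed text
    expect_true(all(f$start >= 0L & f$end <= nchar(cs$text)))
  }
})

test_that("numeric values are invariant to case and surrounding whitespace", {
  base <- parse_numeric("2x10", .rules)
  for (variant in c("  2x10  ", "2X10", "2 x 10", " 2 X 10 ")) {
    v <- parse_numeric(variant, .rules)
    expect_equal(v[order(v$kind), c("kind", "value")],
                 base[order(base$kind), c("kind", "value")],
                 ignore_attr = TRUE, info = variant)
  }
})

test_that("locomotion context reads apostrophe quantities as distance", {
  f <- parse_numeric("tandem walking: 25' x 2", .rules)
  expect_false("duration_seconds" %in% f$kind)   # 25 feet, not 25 minutes
  expect_equal(f$value[f$kind == "reps"], 2L)
  d <- attr(f, "distances")
  expect_equal(d$value, 25L)
})

test_that("projection is a set union with first-occurrence numerics", {
  m <- data.frame(concept_id = c("side.right", "loc.elbow", "plane.flexion",
                                 "plane.flexion"),
                  start = c(0L, 6L, 12L, 20L), end = c(5L, 11L, 19L, 27L),
                  matched_text = c("right", "elbow", "flexion", "flexion"),
                  stringsAsFactors = FALSE)
  n <- data.frame(kind = c("reps", "reps"), value = c(10L, 20L),
                  start = c(30L, 40L), end = c(34L, 44L),
                  unit_normalized = FALSE, stringsAsFactors = FALSE)
  lab <- project(m, n, "desc.in_office")
  expect_setequal(lab$binary, c("side.right", "loc.elbow", "plane.flexion",
                                "desc.in_office"))
  expect_equal(sum(lab$binary == "plane.flexion"), 1L)  # set semantics
  expect_equal(lab$reps, 10L)                           # first wins
  expect_equal(attr(lab, "collisions")$reps, c(10L, 20L))

  # idempotent and order-insensitive in the binary component
  lab2 <- project(m[rev(seq_len(nrow(m))), ], n, "desc.in_office")
  expect_identical(lab$binary, lab2$binary)
})
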