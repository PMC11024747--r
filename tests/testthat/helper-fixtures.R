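# Shared fixtures and independent oracles for the test suite.
# The ontology and rule set load once per test run; corpora are generated
# programmatically at fixed seeds.

.ont <- load_ontology()
.rules <- build_ruleset(.ont)

# The two deidentified therapy-note section examples used across tests:
# run-on numbered lists, heavy with clinical abbreviations.
note_example_1 <- paste(
  "1: AROM right elbow flx/ext HEP (right arm supported on table)",
  "2: AROM right wrist flx/ext HEP",
  "3: AROM right forearm pronation/supination HEP",
  "4: Thumb opposition HEP",
  "5: Seated AAROM table slide??")

note_example_2 <- paste(
  "1: foam balance (heel/toe rocking): x 30",
  "2: step taps with 2 taps from foam 12\"\"\"\" block: x 20 B/L",
  "3: tandem walking: 25' x 2",
  "4: backward walking: 25' x 2",
  "5: foam Lunges: x 20 B/L",
  "6: Dips 4\"\"\"\" stair: 2x10 B/L",
  "7: side stepping green TB 10 ft x5 each direction",
  "9: bridging with LLE leg lift 1\"\"\"\" off mat x10",
  "10: tandem stance on foam x 1'",
  "11: Nustep: L5 x 10' (LEs only)")

# Independent brute-force enrichment oracle: reads the ontology YAML
# directly and counts scoring groups with a keyword hit, using its own
# boundary logic (no shared code with enrichment_score()).
brute_force_enrichment <- function(text,
                                   path = default_ontology_path()) {
  doc <- yaml::read_yaml(path)
  hit_groups <- character(0)
  for (cat in doc$categories) {
    if (!isTRUE(cat$scoring)) next
    group <- if (is.null(cat$score_group)) cat$name else cat$score_group
    pats <- character(0)
    for (k in cat$keywords) {
      pats <- c(pats, if (isTRUE(k$regex)) k$pattern else {
        e <- gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", k$pattern)
        gsub(" +", "\\\\s+", e)
      })
    }
    for (con in cat$concepts) {
      for (e in con$lexicon) {
        esc <- gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", e$pattern)
        esc <- gsub(" +", "\\\\s+", esc)
        esc <- gsub("-", "[-\\\\s]", esc)
        pats <- c(pats, esc)
      }
    }
    found <- FALSE
    for (p in pats) {
      full <- paste0("(?i)(?<![A-Za-z0-9])(?:", p, ")(?![A-Za-z0-9])")
      if (grepl(full, text, perl = TRUE)) { found <- TRUE; break }
    }
    if (found) hit_groups <- c(hit_groups, group)
  }
  length(unique(hit_groups))
}

# Brute-force per-concept confusion-matrix oracle for sequence metrics.
brute_force_sequence_metrics <- function(pred, gold, concepts) {
  out <- list()
  for (cid in concepts) {
    tp <- fp <- fn <- 0L
    for (sid in names(gold)) {
      p <- cid %in% pred[[sid]]
      g <- cid %in% gold[[sid]]
      if (p && g) tp <- tp + 1L
      if (p && !g) fp <- fp + 1L
      if (!p && g) fn <- fn + 1L
    }
    prec <- if (tp + fp > 0) tp / (tp + fp) else 0
    rec <- if (tp + fn > 0) tp / (tp + fn) else 0
    f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
    out[[cid]] <- c(tp = tp, fp = fp, fn = fn,
                    precision = prec, recall = rec, f1 = f1)
  }
  out
}

# Flatteners over gold corpora (mirrors of the pipeline's internals, local
# to the tests).
flat_texts <- function(corpus) rehabext:::corpus_sequence_texts(corpus)
flat_labels <- function(corpus) rehabext:::corpus_sequence_labels(corpus)
flat_numerics <- function(corpus) rehabext:::corpus_numeric_findings(corpus)
rule_preds <- function(corpus, rules = .rules) {
  rehabext:::rule_predictions(corpus, rules)
}
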