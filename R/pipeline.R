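# End-to-end pipeline: simulate (or load) sections -> rule-based extraction
# -> optional per-concept model training -> evaluation, with a JSON run
# manifest for reproducibility.

# Gold corpus -> flat helpers shared by the pipeline and the tests.
corpus_sequence_texts <- function(corpus) {
  unlist(lapply(corpus, function(sec)
    vapply(sec$sequences, `[[`, character(1), "text")), use.names = FALSE)
}

corpus_sequence_ids <- function(corpus) {
  unlist(lapply(corpus, function(sec)
    paste0(sec$id, "#", vapply(sec$sequences, `[[`, character(1),
                               "index_label"))), use.names = FALSE)
}

corpus_sequence_labels <- function(corpus) {
  out <- unlist(lapply(corpus, function(sec)
    lapply(sec$sequences, function(sq) sq$labels$binary)), recursive = FALSE)
  stats::setNames(out, corpus_sequence_ids(corpus))
}

corpus_numeric_findings <- function(corpus) {
  ids <- corpus_sequence_ids(corpus)
  rows <- list()
  i <- 0L
  for (sec in corpus) {
    for (sq in sec$sequences) {
      i <- i + 1L
      for (kind in c("duration_seconds", "sets", "reps")) {
        v <- sq$labels[[kind]]
        if (!is.null(v) && !is.na(v)) {
          rows[[length(rows) + 1L]] <- data.frame(
            sequence_id = ids[i], kind = kind, value = as.integer(v),
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (length(rows)) do.call(rbind, rows) else
    data.frame(sequence_id = character(0), kind = character(0),
               value = integer(0), stringsAsFactors = FALSE)
}

# Run the rule extractor over a gold corpus's section texts, aligning
# predicted sequences to gold sequences by printed item number.
rule_predictions <- function(corpus, ruleset) {
  preds <- list()
  numerics <- list()
  for (sec in corpus) {
    ext <- extract_labels(sec$text, ruleset)
    ext_labels <- stats::setNames(
      lapply(ext, function(e) e$labels$binary),
      vapply(ext, `[[`, character(1), "index_label"))
    for (sq in sec$sequences) {
      sid <- paste0(sec$id, "#", sq$index_label)
      preds[[sid]] <- ext_labels[[sq$index_label]] %||% character(0)
    }
    for (e in ext) {
      sid <- paste0(sec$id, "#", e$index_label)
      for (kind in c("duration_seconds", "sets", "reps")) {
        v <- e$labels[[kind]]
        if (!is.na(v)) {
          numerics[[length(numerics) + 1L]] <- data.frame(
            sequence_id = sid, kind = kind, value = v,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  list(
    labels = preds,
    numerics = if (length(numerics)) do.call(rbind, numerics) else
      data.frame(sequence_id = character(0), kind = character(0),
                 value = integer(0), stringsAsFactors = FALSE)
  )
}

#' Run the end-to-end extraction pipeline
#'
#' Stages, in data-flow order: generate a synthetic gold corpus (or read
#' one from `config$gold_path`), run rule-based extraction over its
#' sections, optionally train and apply the per-concept model bank on a
#' train/test split, and score everything against gold. All intermediates
#' are written as JSONL beside a JSON run manifest; a rerun with the same
#' config and seed is byte-identical for the deterministic stages.
#'
#' @param config A named list (or path to a YAML file): `out_dir`
#'   (required), `seed`, `n_sections`, `gold_path` (optional pre-generated
#'   corpus), `families` (optional character vector: train these model
#'   families), `generator` (overrides merged into
#'   [default_generator_config()]), `ontology_path`, `rules_path`.
#' @return Invisibly, a list with the gold corpus, rule predictions, the
#'   evaluation reports and the manifest.
#' @export
run_end_to_end <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(config$out_dir)) stop("config$out_dir is required")
  seed <- as.integer(config$seed %||% 1L)
  started <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")

  ontology <- load_ontology(config$ontology_path %||% default_ontology_path())
  ruleset <- build_ruleset(ontology, config$rules_path %||% default_rules_path())
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)

  gen_cfg <- utils::modifyList(default_generator_config(),
                               config$generator %||% list())
  corpus <- if (!is.null(config$gold_path)) {
    read_gold(config$gold_path)
  } else {
    generate_corpus(config$n_sections %||% 100L, gen_cfg, ontology, seed = seed)
  }
  gold_path <- file.path(config$out_dir, "gold.jsonl")
  export_gold(corpus, gold_path)

  rp <- rule_predictions(corpus, ruleset)
  gold_labels <- corpus_sequence_labels(corpus)
  pred_path <- file.path(config$out_dir, "pred_rules.jsonl")
  write_jsonl(lapply(names(rp$labels), function(sid)
    list(sequence_id = sid, binary = as.list(rp$labels[[sid]]))), pred_path)

  report <- list(
    rules_sequence = sequence_metrics(rp$labels, gold_labels,
                                      concepts = ontology$binary_ids),
    rules_numeric = numeric_metrics(rp$numerics,
                                    corpus_numeric_findings(corpus))
  )

  if (!is.null(config$families)) {
    ids <- names(gold_labels)
    texts <- stats::setNames(corpus_sequence_texts(corpus), ids)
    split <- split_train_test(
      ids[seq_len(floor(length(ids) / 2))],
      ids[seq(floor(length(ids) / 2) + 1L, length(ids))],
      n_train_each = floor(length(ids) * 5 / 12), seed = seed)
    bank <- train_all(texts[split$train], gold_labels[split$train], ontology,
                      families = config$families)
    for (fam in config$families) {
      pm <- predict_bank(bank, texts[split$test], fam)
      pl <- stats::setNames(lapply(seq_len(nrow(pm)), function(i)
        colnames(pm)[pm[i, ] == 1L]), split$test)
      report[[paste0("ml_", fam)]] <- sequence_metrics(
        pl, gold_labels[split$test], concepts = ontology$binary_ids)
    }
  }

  report_path <- file.path(config$out_dir, "report.json")
  jsonlite::write_json(
    lapply(report, function(r) {
      if (inherits(r, "rehab_eval")) list(macro = r$macro,
                                          per_concept = r$per_concept)
      else r
    }),
    report_path, auto_unbox = TRUE, digits = NA, dataframe = "rows")

  manifest <- list(
    command = "run_end_to_end",
    seed = seed,
    ontology_version = ontology$version,
    rules_version = ruleset$version,
    n_sections = length(corpus),
    started = started,
    finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    outputs = list(gold = gold_path, predictions = pred_path,
                   report = report_path)
  )
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(corpus = corpus, rule_predictions = rp, report = report,
                 manifest = manifest))
}
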