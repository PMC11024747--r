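# The clinical ontology: categories, concepts and surface-form lexicons.
#
# The shipped configuration (inst/extdata/ontology.yaml) transcribes the
# nine exercise-information categories -- type of motion, side of body,
# location on body, plane of motion, duration, sets, reps, exercise purpose,
# exercise type, body position -- plus the exercise-description labels
# (performed in-office, home exercise program, not performed). The
# enumerated and binary categories carry 101 binary-classifiable concepts;
# duration, sets and reps are integer-valued and hold no concepts, only
# category-level keywords used by the section enrichment score.

#' Path to the packaged ontology configuration
#' @return File path of the shipped ontology YAML.
#' @export
default_ontology_path <- function() {
  system.file("extdata", "ontology.yaml", package = "rehabext", mustWork = TRUE)
}

#' Load and validate a clinical ontology
#'
#' Reads an ontology configuration (YAML with top-level `categories:`) and
#' validates it: globally unique concept ids, non-empty lexicon patterns
#' that compile, integer categories free of enumerated concepts, and --
#' unless disabled -- the expected number of binary-classifiable concepts
#' and of scoring groups.
#'
#' @param path Configuration file; defaults to the packaged ontology.
#' @param expect_binary Expected count of binary-classifiable concepts
#'   (all concepts of enumerated/binary categories). `NULL` skips the check;
#'   the shipped ontology has 101.
#' @param expect_scoring_groups Expected number of distinct scoring groups
#'   participating in the 0-9 enrichment score (`NULL` to skip; shipped: 9).
#' @return An object of class `rehab_ontology`.
#' @export
load_ontology <- function(path = default_ontology_path(),
                          expect_binary = 101L,
                          expect_scoring_groups = 9L) {
  if (!file.exists(path)) stop("ontology config not found: ", path)
  doc <- yaml::read_yaml(path)
  if (is.null(doc$categories) || length(doc$categories) == 0L) {
    stop("ontology config has no categories: ", path)
  }

  categories <- lapply(doc$categories, function(cat) {
    stopifnot(!is.null(cat$name), !is.null(cat$data_type))
    if (!cat$data_type %in% c("enumerated", "integer", "binary")) {
      stop("category '", cat$name, "': unknown data_type '", cat$data_type, "'")
    }
    concepts <- lapply(cat$concepts, function(con) {
      if (is.null(con$id) || !nzchar(con$id)) {
        stop("category '", cat$name, "': concept without id")
      }
      lex <- lapply(con$lexicon, function(e) {
        if (is.null(e$pattern) || !nzchar(e$pattern)) {
          stop("concept '", con$id, "': empty lexicon pattern")
        }
        entry <- list(
          pattern = e$pattern,
          regex = isTRUE(e$regex),
          case_sensitive = isTRUE(e$case_sensitive)
        )
        entry$compiled <- compile_lexicon_pattern(entry$pattern, entry$regex,
                                                  entry$case_sensitive)
        ok <- tryCatch({grepl(entry$compiled, "probe", perl = TRUE); TRUE},
                       error = function(e) FALSE)
        if (!ok) stop("concept '", con$id, "': lexicon regex does not compile: ",
                      entry$pattern)
        entry
      })
      list(id = con$id, name = con$name %||% con$id,
           category = cat$name, lexicon = lex)
    })
    if (cat$data_type == "integer" && length(concepts) > 0L) {
      stop("integer category '", cat$name, "' must not contain enumerated concepts")
    }
    keywords <- lapply(cat$keywords, function(e) {
      if (is.null(e$pattern) || !nzchar(e$pattern)) {
        stop("category '", cat$name, "': empty scoring keyword")
      }
      list(pattern = e$pattern, regex = isTRUE(e$regex))
    })
    list(name = cat$name,
         data_type = cat$data_type,
         scoring = isTRUE(cat$scoring),
         score_group = cat$score_group %||% cat$name,
         keywords = keywords,
         concepts = concepts)
  })
  names(categories) <- vapply(categories, `[[`, character(1), "name")

  ids <- unlist(lapply(categories, function(cat)
    vapply(cat$concepts, `[[`, character(1), "id")), use.names = FALSE)
  dup <- ids[duplicated(ids)]
  if (length(dup)) stop("duplicate concept id(s): ", paste(unique(dup), collapse = ", "))

  binary_ids <- unlist(lapply(categories, function(cat) {
    if (cat$data_type == "integer") character(0)
    else vapply(cat$concepts, `[[`, character(1), "id")
  }), use.names = FALSE)
  if (!is.null(expect_binary) && length(binary_ids) != expect_binary) {
    stop("expected ", expect_binary, " binary-classifiable concepts, found ",
         length(binary_ids))
  }

  scoring_groups <- unique(vapply(
    Filter(function(cat) cat$scoring, categories),
    `[[`, character(1), "score_group"))
  if (!is.null(expect_scoring_groups) &&
      length(scoring_groups) != expect_scoring_groups) {
    stop("expected ", expect_scoring_groups, " scoring groups, found ",
         length(scoring_groups), " (", paste(scoring_groups, collapse = ", "), ")")
  }

  concept_rows <- do.call(rbind, unlist(lapply(categories, function(cat) {
    lapply(cat$concepts, function(con) {
      data.frame(id = con$id, name = con$name, category = cat$name,
                 n_lexicon = length(con$lexicon), stringsAsFactors = FALSE)
    })
  }), recursive = FALSE))
  rownames(concept_rows) <- NULL

  structure(list(
    version = doc$version %||% "unversioned",
    categories = categories,
    concepts = concept_rows,
    binary_ids = binary_ids,
    scoring_groups = scoring_groups
  ), class = "rehab_ontology")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.rehab_ontology <- function(x, ...) {
  cat("Clinical rehabilitation-exercise ontology (version ", x$version, ")\n",
      sep = "")
  cat("  ", length(x$categories), " categories, ",
      nrow(x$concepts), " concepts (", length(x$binary_ids),
      " binary-classifiable)\n", sep = "")
  cat("  scoring groups:", paste(x$scoring_groups, collapse = ", "), "\n")
  invisible(x)
}

# Internal: the concept list of one category.
ontology_category <- function(ontology, name) {
  cat <- ontology$categories[[name]]
  if (is.null(cat)) stop("no such category: ", name)
  cat
}

# Internal: flat table of (concept_id, pattern, regex, case_sensitive,
# compiled) covering every lexicon entry.
ontology_lexicon <- function(ontology) {
  rows <- unlist(lapply(ontology$categories, function(cat) {
    lapply(cat$concepts, function(con) {
      if (length(con$lexicon) == 0L) return(NULL)
      data.frame(
        concept_id = con$id,
        category = cat$name,
        pattern = vapply(con$lexicon, `[[`, character(1), "pattern"),
        regex = vapply(con$lexicon, function(e) isTRUE(e$regex), logical(1)),
        case_sensitive = vapply(con$lexicon, function(e)
          isTRUE(e$case_sensitive), logical(1)),
        compiled = vapply(con$lexicon, `[[`, character(1), "compiled"),
        stringsAsFactors = FALSE
      )
    })
  }), recursive = FALSE)
  out <- do.call(rbind, Filter(Negate(is.null), rows))
  rownames(out) <- NULL
  out
}

#' Look up the concepts whose lexicon matches a surface form
#'
#' The whole surface string must match a lexicon entry (token boundaries
#' included), so `"AROM"` resolves to Active ROM while `"xyzzy"` resolves to
#' nothing. A surface may map to several concepts: the bare token `"ROM"`
#' names both the type-of-motion concept and the range-of-motion exercise
#' type, and compound laterality abbreviations such as `"LUE"` name a side
#' and a location at once.
#'
#' @param ontology A loaded `rehab_ontology`.
#' @param surface A single token or phrase.
#' @return A data.frame of matching concepts (id, name, category); zero rows
#'   when nothing matches.
#' @export
lookup <- function(ontology, surface) {
  stopifnot(inherits(ontology, "rehab_ontology"),
            is.character(surface), length(surface) == 1L)
  lex <- ontology_lexicon(ontology)
  full <- paste0("^(?:", sub("\\(\\?i\\)", "", lex$compiled, fixed = FALSE), ")$")
  full <- ifelse(grepl("^\\(\\?i\\)", lex$compiled), paste0("(?i)", full), full)
  hit <- vapply(seq_len(nrow(lex)), function(i) {
    grepl(full[i], surface, perl = TRUE)
  }, logical(1))
  ids <- unique(lex$concept_id[hit])
  ontology$concepts[match(ids, ontology$concepts$id), , drop = FALSE]
}
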