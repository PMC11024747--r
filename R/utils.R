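# Shared internal helpers: pattern compilation, tokenization, seeded RNG,
# JSONL round-tripping.

# Compile one lexicon entry into a PCRE pattern with token boundaries.
# Literal entries get their regex metacharacters escaped, internal spaces
# relaxed to \s+ and hyphens to [-\s]; both ends are guarded so that a match
# can never start or end inside an alphanumeric token ("extension" must not
# fire "tension", "LE" must not fire inside "LEs").
compile_lexicon_pattern <- function(pattern, regex = FALSE, case_sensitive = FALSE) {
  stopifnot(is.character(pattern), length(pattern) == 1L, nzchar(pattern))
  body <- if (isTRUE(regex)) {
    pattern
  } else {
    esc <- gsub("([\\^$.|?*+()\\[\\]{}\\\\])", "\\\\\\1", pattern, perl = TRUE)
    esc <- gsub(" +", "\\\\s+", esc)
    gsub("-", "[-\\\\s]", esc, fixed = FALSE)
  }
  flags <- if (isTRUE(case_sensitive)) "" else "(?i)"
  paste0(flags, "(?<![A-Za-z0-9])(?:", body, ")(?![A-Za-z0-9])")
}

# Locate all matches of a compiled pattern; returns a data.frame with
# 0-based, half-open character offsets.
pattern_matches <- function(text, compiled) {
  m <- gregexpr(compiled, text, perl = TRUE)[[1]]
  if (m[1] == -1L) {
    return(data.frame(start = integer(0), end = integer(0),
                      text = character(0), stringsAsFactors = FALSE))
  }
  len <- attr(m, "match.length")
  data.frame(
    start = as.integer(m) - 1L,
    end = as.integer(m) - 1L + len,
    text = substring(text, m, m + len - 1L),
    stringsAsFactors = FALSE
  )
}

# Uncased bag-of-words tokenizer: casefold, then split on non-alphanumeric
# runs. Digit-bearing compounds such as "2x10" survive as single tokens.
tokenize_text <- function(x) {
  x <- tolower(x)
  toks <- strsplit(x, "[^a-z0-9]+")
  lapply(toks, function(t) t[nzchar(t)])
}

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's stream afterwards.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

normalize_newlines <- function(x) gsub("\r\n?", "\n", x)

#' Write records to a JSON Lines file
#'
#' One JSON object per line; used for sections, gold corpora, predictions
#' and reports so that gold and predicted annotations diff directly.
#'
#' @param records A list of records (each coercible to a JSON object).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_jsonl <- function(records, path) {
  lines <- vapply(records, function(r) {
    as.character(jsonlite::toJSON(r, auto_unbox = TRUE, digits = NA, null = "null"))
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read a JSON Lines file
#'
#' @param path File written by [write_jsonl()].
#' @return A list of records.
#' @export
read_jsonl <- function(path) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  lapply(lines, function(l) jsonlite::fromJSON(l, simplifyDataFrame = FALSE))
}
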