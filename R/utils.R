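# Internal helpers shared across modules.

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so package functions that take a `seed`
#' argument never disturb the caller's RNG stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single integer", call. = FALSE)
  }
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Canonical key for an itemset: sorted, joined on the field separator used in
# all TSV interchange. Disease terms must not contain ";".
itemset_key <- function(items) paste(sort(items), collapse = ";")

split_key <- function(key) strsplit(key, ";", fixed = TRUE)[[1L]]

# Canonical undirected edge representation: lexicographically ordered pair.
canonical_edges <- function(from, to) {
  swap <- from > to
  tmp <- from[swap]
  from[swap] <- to[swap]
  to[swap] <- tmp
  data.frame(from = from, to = to, stringsAsFactors = FALSE)
}

# Lowercase + collapse internal whitespace + trim; the comparison form used
# for term-map lookups.
normalize_term <- function(x) {
  x <- tolower(trimws(x))
  gsub("[[:space:]]+", " ", x)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
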