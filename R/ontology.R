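# Disease ontology support: a rooted DAG of is_a relations, a structural
# information-content measure, and Resnik semantic similarity.
#
# The similarity of two diseases is the information content, -log p(a), of
# their most informative common ancestor a. p(a) is the structural
# descendant-fraction variant: the fraction of ontology terms subsumed by a
# (including a itself), so the root has p = 1 and IC 0, and deeper terms are
# more informative.

#' Construct an ontology
#'
#' @param terms character vector of all term names.
#' @param parents named list: term -> character vector of parent terms
#'   (is_a). Roots are terms with no parents. The graph must be acyclic.
#' @return an object of class `ontology` with fields `terms`, `parents`,
#'   `roots`, and (after [information_content()]) `p`.
#' @export
ontology <- function(terms, parents) {
  terms <- unique(as.character(terms))
  parents <- parents[intersect(names(parents), terms)]
  for (ch in names(parents)) {
    bad <- setdiff(parents[[ch]], terms)
    if (length(bad) > 0L) {
      stop("parent term(s) not in `terms`: ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
  }
  ont <- structure(
    list(terms = terms, parents = parents,
         roots = setdiff(terms, names(parents)[lengths(parents) > 0L]),
         p = NULL),
    class = "ontology"
  )
  if (is.null(topological_order(ont))) {
    stop("ontology is cyclic: is_a relations must form a DAG", call. = FALSE)
  }
  ont
}

#' @export
print.ontology <- function(x, ...) {
  cat("Ontology:", length(x$terms), "terms,",
      length(x$roots), "root(s)",
      if (!is.null(x$p)) "(information content populated)" else "", "\n")
  invisible(x)
}

# Kahn topological sort child-before-parent... we orient edges child -> parent
# and return an order in which every term precedes its parents; NULL on cycle.
topological_order <- function(ont) {
  n <- length(ont$terms)
  idx <- stats::setNames(seq_len(n), ont$terms)
  out_deg <- rep(0L, n)           # number of parents not yet emitted
  children_of <- vector("list", n)
  for (ch in names(ont$parents)) {
    for (pa in ont$parents[[ch]]) {
      out_deg[idx[ch]] <- out_deg[idx[ch]] + 1L
      children_of[[idx[pa]]] <- c(children_of[[idx[pa]]], idx[ch])
    }
  }
  # start from terms with no parents (roots), walk down to children
  queue <- which(out_deg == 0L)
  emitted <- integer(0L)
  remaining_parents <- out_deg
  while (length(queue) > 0L) {
    v <- queue[[1L]]; queue <- queue[-1L]
    emitted <- c(emitted, v)
    for (ch in children_of[[v]]) {
      remaining_parents[ch] <- remaining_parents[ch] - 1L
      if (remaining_parents[ch] == 0L) queue <- c(queue, ch)
    }
  }
  if (length(emitted) < n) return(NULL)
  ont$terms[emitted]
}

#' Ancestors of a term
#'
#' Every term on an is_a path from `term` upward; by the convention used for
#' Resnik similarity, a term is its own ancestor.
#'
#' @param ont an `ontology`.
#' @param term a term name.
#' @param include_self include `term` itself (default TRUE).
#' @return character vector of ancestor terms.
#' @export
ancestors <- function(ont, term, include_self = TRUE) {
  stopifnot(inherits(ont, "ontology"))
  if (!term %in% ont$terms) {
    stop("term '", term, "' is not in the ontology", call. = FALSE)
  }
  seen <- character(0L)
  frontier <- term
  while (length(frontier) > 0L) {
    seen <- union(seen, frontier)
    frontier <- setdiff(
      unique(unlist(ont$parents[frontier], use.names = FALSE)), seen)
  }
  if (include_self) seen else setdiff(seen, term)
}

#' Populate structural information content
#'
#' Sets `p(a) = |descendants(a) including a| / |terms|` for every term, so
#' a root subsuming all terms gets p = 1 (information content 0) and leaves
#' get the smallest p. p is monotone non-decreasing from child to ancestor.
#'
#' @param ont an `ontology`.
#' @param mode only `"descendant_fraction"` is implemented.
#' @return the ontology with `p` populated (named numeric vector).
#' @export
information_content <- function(ont, mode = "descendant_fraction") {
  stopifnot(inherits(ont, "ontology"))
  mode <- match.arg(mode, "descendant_fraction")
  n <- length(ont$terms)
  # descendant sets bottom-up: reverse topological order (children first)
  topo <- topological_order(ont)   # parents-before-children
  desc <- stats::setNames(vector("list", n), ont$terms)
  for (term in rev(topo)) {
    d <- term
    # children of `term`
    for (ch in names(ont$parents)) {
      if (term %in% ont$parents[[ch]]) d <- union(d, desc[[ch]])
    }
    desc[[term]] <- d
  }
  ont$p <- vapply(desc, function(d) length(d) / n, numeric(1L))[ont$terms]
  ont
}

#' Resnik semantic similarity of two diseases
#'
#' `max` over all common ancestors a of `-log p(a)` (natural log); each term
#' counts as its own ancestor, so `resnik_similarity(d, d) = -log p(d)`, and
#' two terms whose only common ancestor is an all-subsuming root score 0.
#'
#' @param d1,d2 term names (a key error names the missing term).
#' @param ont an `ontology` with `p` populated (see [information_content()];
#'   called implicitly if missing).
#' @return non-negative similarity.
#' @export
resnik_similarity <- function(d1, d2, ont) {
  stopifnot(inherits(ont, "ontology"))
  if (is.null(ont$p)) ont <- information_content(ont)
  common <- intersect(ancestors(ont, d1), ancestors(ont, d2))
  if (length(common) == 0L) return(0)
  max(-log(ont$p[common]))
}

#' Write / read the parent-child TSV interchange format
#'
#' Columns `child`, `parent`, one row per is_a relation; roots appear with
#' an empty `parent` field so isolated roots survive the round trip.
#'
#' @param ont an `ontology`.
#' @param path TSV path.
#' @export
write_ontology_tsv <- function(ont, path) {
  stopifnot(inherits(ont, "ontology"))
  child <- rep(names(ont$parents), lengths(ont$parents))
  parent <- unlist(ont$parents, use.names = FALSE)
  roots <- setdiff(ont$terms, child)
  df <- data.frame(child = c(child, roots),
                   parent = c(parent, rep("", length(roots))),
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_ontology_tsv
#' @export
read_ontology_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, quote = "",
                          comment.char = "", colClasses = "character",
                          stringsAsFactors = FALSE)
  if (!all(c("child", "parent") %in% names(df))) {
    stop("ontology TSV must have columns child and parent", call. = FALSE)
  }
  has_parent <- df$parent != ""
  parents <- split(df$parent[has_parent], df$child[has_parent])
  ontology(terms = unique(c(df$child, df$parent[has_parent])),
           parents = parents)
}

#' Write / read a minimal OBO serialization
#'
#' Only `[Term]` stanzas with `id`, `name` and `is_a` tags are emitted and
#' parsed — enough for is_a DAGs such as the Disease Ontology's backbone.
#'
#' @param ont an `ontology`.
#' @param path OBO path.
#' @export
write_obo <- function(ont, path) {
  stopifnot(inherits(ont, "ontology"))
  lines <- c("format-version: 1.2", "")
  for (term in ont$terms) {
    lines <- c(lines, "[Term]", paste0("id: ", term), paste0("name: ", term))
    for (pa in ont$parents[[term]] %||% character(0L)) {
      lines <- c(lines, paste0("is_a: ", pa))
    }
    lines <- c(lines, "")
  }
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_obo
#' @export
read_obo <- function(path) {
  lines <- readLines(path, warn = FALSE)
  terms <- character(0L)
  parents <- list()
  cur <- NULL
  in_term <- FALSE
  for (ln in lines) {
    ln <- trimws(ln)
    if (ln == "[Term]") { in_term <- TRUE; cur <- NULL; next }
    if (grepl("^\\[", ln)) { in_term <- FALSE; next }
    if (!in_term || ln == "") next
    if (grepl("^id:", ln)) {
      cur <- trimws(sub("^id:", "", ln))
      terms <- c(terms, cur)
    } else if (grepl("^is_a:", ln) && !is.null(cur)) {
      # strip trailing "! name" comments used by real OBO files
      pa <- trimws(sub("!.*$", "", sub("^is_a:", "", ln)))
      parents[[cur]] <- c(parents[[cur]], pa)
    }
  }
  ontology(terms = unique(c(terms, unlist(parents, use.names = FALSE))),
           parents = parents)
}
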