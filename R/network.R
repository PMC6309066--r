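# Disease comorbidity network (DCN): an undirected, unweighted graph whose
# nodes are diseases and whose edges come from mined association rules.

#' Construct a disease network
#'
#' @param nodes character vector of disease terms.
#' @param edges data.frame with character columns `from`, `to`; stored
#'   canonically (lexicographically ordered pair, no duplicates, no
#'   self-loops). Endpoints must be in `nodes`.
#' @param node_category optional named character vector disease -> category
#'   label (System Organ Class analog); uncategorized nodes get `"Unknown"`.
#' @param provenance free-text note (e.g. the number of rules used).
#' @return an object of class `disease_network`.
#' @export
disease_network <- function(nodes, edges, node_category = NULL,
                            provenance = "") {
  nodes <- sort(unique(as.character(nodes)))
  edges <- canonical_edges(as.character(edges$from), as.character(edges$to))
  if (any(edges$from == edges$to)) stop("self-loops are not allowed", call. = FALSE)
  edges <- unique(edges)
  edges <- edges[order(edges$from, edges$to), , drop = FALSE]
  rownames(edges) <- NULL
  if (!all(c(edges$from, edges$to) %in% nodes)) {
    stop("every edge endpoint must be a network node", call. = FALSE)
  }
  category <- stats::setNames(rep("Unknown", length(nodes)), nodes)
  if (!is.null(node_category)) {
    known <- intersect(names(node_category), nodes)
    category[known] <- node_category[known]
  }
  structure(list(nodes = nodes, edges = edges, node_category = category,
                 provenance = provenance),
            class = "disease_network")
}

#' @export
print.disease_network <- function(x, ...) {
  cat("Disease network:", length(x$nodes), "nodes,", nrow(x$edges), "edges")
  if (nzchar(x$provenance)) cat(" (", x$provenance, ")", sep = "")
  cat("\n")
  invisible(x)
}

#' Build the comorbidity network from association rules
#'
#' Nodes are all diseases appearing on either side of any rule. With
#' `edge_policy = "cross_only"` (default) an edge joins each antecedent
#' disease to each consequent disease of a rule; with `"clique"` every pair
#' of diseases within a rule's full itemset is joined. Duplicate edges
#' across rules collapse; the network is undirected and unweighted.
#'
#' @param rules an `association_rules` data.frame (see [generate_rules()]).
#' @param edge_policy `"cross_only"` or `"clique"`.
#' @param node_category optional named character vector of category labels.
#' @return a `disease_network`.
#' @export
build_network <- function(rules, edge_policy = c("cross_only", "clique"),
                          node_category = NULL) {
  edge_policy <- match.arg(edge_policy)
  if (nrow(rules) == 0L) {
    warning("no rules supplied: returning an empty network", call. = FALSE)
    return(disease_network(character(0L),
                           data.frame(from = character(0L), to = character(0L)),
                           node_category, provenance = "0 rules"))
  }
  from <- character(0L); to <- character(0L)
  for (i in seq_len(nrow(rules))) {
    x <- split_key(rules$antecedent[i])
    y <- split_key(rules$consequent[i])
    if (edge_policy == "cross_only") {
      pairs <- expand.grid(x, y, stringsAsFactors = FALSE)
      from <- c(from, pairs[[1L]]); to <- c(to, pairs[[2L]])
    } else {
      all_items <- sort(unique(c(x, y)))
      if (length(all_items) >= 2L) {
        pairs <- utils::combn(all_items, 2L)
        from <- c(from, pairs[1L, ]); to <- c(to, pairs[2L, ])
      }
    }
  }
  disease_network(unique(c(from, to)), data.frame(from = from, to = to),
                  node_category,
                  provenance = paste(nrow(rules), "rules,", edge_policy))
}

#' Neighbors of a disease in the network
#'
#' @param net a `disease_network`.
#' @param disease a node term.
#' @return character vector of adjacent diseases (never contains the query).
#' @export
neighbors <- function(net, disease) {
  stopifnot(inherits(net, "disease_network"))
  if (!disease %in% net$nodes) {
    stop("disease '", disease, "' is not a network node", call. = FALSE)
  }
  sort(unique(c(net$edges$to[net$edges$from == disease],
                net$edges$from[net$edges$to == disease])))
}

#' Descriptive properties of the network
#'
#' @param net a `disease_network`.
#' @return a list: `n_nodes`, `n_edges`, `density` (2|E| / (|V|(|V|-1)); 0
#'   for a single-node network), `degree` (named integer vector), and
#'   `degree_summary` (min/median/max).
#' @export
network_properties <- function(net) {
  stopifnot(inherits(net, "disease_network"))
  n <- length(net$nodes)
  m <- nrow(net$edges)
  deg <- stats::setNames(rep(0L, n), net$nodes)
  tab <- table(c(net$edges$from, net$edges$to))
  deg[names(tab)] <- as.integer(tab)
  list(
    n_nodes = n,
    n_edges = m,
    density = if (n < 2L) 0 else 2 * m / (n * (n - 1)),
    degree = deg,
    degree_summary = c(min = if (n) min(deg) else NA_integer_,
                       median = if (n) stats::median(deg) else NA_real_,
                       max = if (n) max(deg) else NA_integer_)
  )
}

# Integer adjacency list representation used by graph algorithms; nodes are
# indexed in the order of net$nodes.
adjacency_list <- function(nodes, edges) {
  idx <- stats::setNames(seq_along(nodes), nodes)
  adj <- vector("list", length(nodes))
  for (i in seq_along(adj)) adj[[i]] <- integer(0L)
  if (nrow(edges) > 0L) {
    f <- idx[edges$from]; t <- idx[edges$to]
    for (k in seq_along(f)) {
      adj[[f[k]]] <- c(adj[[f[k]]], t[k])
      adj[[t[k]]] <- c(adj[[t[k]]], f[k])
    }
  }
  adj
}

# Connected components via BFS; returns an integer vector of component ids
# (1-based, in order of first node encountered) named by node.
graph_components <- function(nodes, edges) {
  adj <- adjacency_list(nodes, edges)
  comp <- rep(NA_integer_, length(nodes))
  cid <- 0L
  for (s in seq_along(nodes)) {
    if (!is.na(comp[s])) next
    cid <- cid + 1L
    queue <- s
    comp[s] <- cid
    while (length(queue) > 0L) {
      v <- queue[[1L]]
      queue <- queue[-1L]
      for (w in adj[[v]]) {
        if (is.na(comp[w])) {
          comp[w] <- cid
          queue <- c(queue, w)
        }
      }
    }
  }
  stats::setNames(comp, nodes)
}

#' Write / read a network as edge-list + node-attribute TSVs
#'
#' `write_network()` writes `<dir>/edges.tsv` (columns `from`, `to`,
#' lexicographic pair order) and `<dir>/nodes.tsv` (columns `disease`,
#' `category`).
#'
#' @param net a `disease_network`.
#' @param dir directory (created if needed).
#' @return the directory / the network.
#' @export
write_network <- function(net, dir) {
  stopifnot(inherits(net, "disease_network"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(net$edges, file.path(dir, "edges.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(disease = net$nodes, category = unname(net$node_category),
               stringsAsFactors = FALSE),
    file.path(dir, "nodes.tsv"), sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(dir)
}

#' @rdname write_network
#' @export
read_network <- function(dir) {
  edges <- utils::read.table(file.path(dir, "edges.tsv"), sep = "\t",
                             header = TRUE, quote = "", comment.char = "",
                             colClasses = "character")
  nodes <- utils::read.table(file.path(dir, "nodes.tsv"), sep = "\t",
                             header = TRUE, quote = "", comment.char = "",
                             colClasses = "character")
  disease_network(nodes$disease, edges,
                  stats::setNames(nodes$category, nodes$disease),
                  provenance = paste("read from", dir))
}
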