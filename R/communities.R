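# Divisive community detection on the comorbidity network: Girvan-Newman
# edge removal guided by edge betweenness, with the partition chosen by
# maximizing Newman-Girvan modularity measured on the ORIGINAL network, plus
# per-cluster category (SOC) enrichment.

# Brandes-style single-source accumulation of edge betweenness, summed over
# all sources; each unordered pair is visited from both endpoints, so the
# total is halved at the end.
edge_betweenness_impl <- function(nodes, edges) {
  n <- length(nodes)
  m <- nrow(edges)
  if (m == 0L) return(stats::setNames(numeric(0L), character(0L)))
  idx <- stats::setNames(seq_len(n), nodes)
  ef <- idx[edges$from]; et <- idx[edges$to]
  # edge lookup: key on min*n + max of the endpoint indices
  ekey <- function(a, b) pmin(a, b) * (n + 1L) + pmax(a, b)
  eb <- stats::setNames(numeric(m), ekey(ef, et))
  adj <- adjacency_list(nodes, edges)
  for (s in seq_len(n)) {
    # BFS from s: sigma = number of shortest paths, dist, predecessor lists
    sigma <- numeric(n); sigma[s] <- 1
    dist <- rep(-1L, n); dist[s] <- 0L
    preds <- vector("list", n)
    order_visited <- integer(0L)
    queue <- s
    while (length(queue) > 0L) {
      v <- queue[[1L]]; queue <- queue[-1L]
      order_visited <- c(order_visited, v)
      for (w in adj[[v]]) {
        if (dist[w] < 0L) {
          dist[w] <- dist[v] + 1L
          queue <- c(queue, w)
        }
        if (dist[w] == dist[v] + 1L) {
          sigma[w] <- sigma[w] + sigma[v]
          preds[[w]] <- c(preds[[w]], v)
        }
      }
    }
    # dependency accumulation, deepest first; delta[v] = sum over paths
    delta <- numeric(n)
    for (w in rev(order_visited)) {
      for (v in preds[[w]]) {
        contrib <- sigma[v] / sigma[w] * (1 + delta[w])
        key <- as.character(ekey(v, w))
        eb[key] <- eb[key] + contrib
        delta[v] <- delta[v] + contrib
      }
    }
  }
  # each unordered (s, t) pair contributed from both s and t
  stats::setNames(eb / 2, paste(edges$from, edges$to, sep = ";")[
    match(names(eb), as.character(ekey(ef, et)))])
}

#' Edge betweenness centrality
#'
#' For each edge, the sum over unordered node pairs (s, t) of the fraction
#' of shortest s-t paths (unweighted) traversing that edge; disconnected
#' pairs contribute nothing. Computed by Brandes-style BFS accumulation.
#'
#' @param net a `disease_network`.
#' @return named numeric vector keyed `"from;to"` in canonical edge order.
#' @examples
#' net <- disease_network(c("a", "b", "c"),
#'                        data.frame(from = c("a", "b"), to = c("b", "c")))
#' edge_betweenness(net)  # both edges carry 2 of the 3 node pairs
#' @export
edge_betweenness <- function(net) {
  stopifnot(inherits(net, "disease_network"))
  eb <- edge_betweenness_impl(net$nodes, net$edges)
  keys <- paste(net$edges$from, net$edges$to, sep = ";")
  stats::setNames(unname(eb[keys]), keys)
}

#' Newman-Girvan modularity of a partition
#'
#' Q = sum over clusters c of (e_c / m - (d_c / 2m)^2), with e_c the number
#' of intra-cluster edges, d_c the total degree of cluster c and m the total
#' edge count, evaluated on the full edge set of `net`.
#'
#' @param net a `disease_network`.
#' @param assignment named vector (cluster ids named by node) covering all
#'   nodes of `net`.
#' @return Q in \[-0.5, 1\]; 0 for an edgeless network by convention.
#' @export
modularity <- function(net, assignment) {
  stopifnot(inherits(net, "disease_network"))
  if (!all(net$nodes %in% names(assignment))) {
    missing <- setdiff(net$nodes, names(assignment))
    stop("assignment missing node(s): ", paste(utils::head(missing, 3L),
                                               collapse = ", "), call. = FALSE)
  }
  m <- nrow(net$edges)
  if (m == 0L) return(0)
  cl_from <- assignment[net$edges$from]
  cl_to <- assignment[net$edges$to]
  deg <- network_properties(net)$degree
  q <- 0
  for (cl in unique(assignment[net$nodes])) {
    e_c <- sum(cl_from == cl & cl_to == cl)
    d_c <- sum(deg[names(assignment)[assignment == cl] |>
                     intersect(net$nodes)])
    q <- q + e_c / m - (d_c / (2 * m))^2
  }
  q
}

#' Girvan-Newman community detection
#'
#' Iteratively removes the single edge of highest betweenness (ties broken
#' by lexicographic edge order), recomputing betweenness on the current
#' graph after every removal. Whenever a removal splits a connected
#' component, the modularity of the current component partition — measured
#' on the original network — is recorded; the returned partition is the one
#' of maximum recorded modularity (ties go to the earlier split, i.e. fewer
#' removals). The component partition of the intact network is recorded
#' first, so a network whose best cut is "no cut" returns it.
#'
#' @param net a `disease_network`.
#' @param min_report_size clusters of at most this many nodes are flagged
#'   unreported (but retained in the assignment).
#' @return an object of class `cluster_partition`: `assignment` (named
#'   integer cluster ids), `modularity_Q`, `removal_trace` (data.frame
#'   `step`, `edge`, `Q` — Q is `NA` on steps without a component split),
#'   `min_report_size`, `reported` (logical per cluster id).
#' @export
girvan_newman <- function(net, min_report_size = 10L) {
  stopifnot(inherits(net, "disease_network"))
  nodes <- net$nodes
  comp0 <- graph_components(nodes, net$edges)
  best_assign <- comp0
  best_q <- modularity(net, comp0)
  cur_edges <- net$edges
  n_comp <- max(comp0, 0L)
  trace_edge <- character(0L)
  trace_q <- numeric(0L)
  step <- 0L
  while (nrow(cur_edges) > 0L) {
    eb <- edge_betweenness_impl(nodes, cur_edges)
    keys <- paste(cur_edges$from, cur_edges$to, sep = ";")
    vals <- eb[keys]
    # max betweenness; tie -> lexicographically smallest canonical edge
    cand <- keys[vals >= max(vals) - 1e-9 * max(1, max(vals))]
    drop_key <- sort(cand)[1L]
    drop_i <- match(drop_key, keys)
    step <- step + 1L
    cur_edges <- cur_edges[-drop_i, , drop = FALSE]
    comp <- graph_components(nodes, cur_edges)
    if (max(comp) > n_comp) {
      n_comp <- max(comp)
      q <- modularity(net, comp)
      trace_edge <- c(trace_edge, drop_key)
      trace_q <- c(trace_q, q)
      if (q > best_q + 1e-12) {
        best_q <- q
        best_assign <- comp
      }
    } else {
      trace_edge <- c(trace_edge, drop_key)
      trace_q <- c(trace_q, NA_real_)
    }
  }
  sizes <- table(best_assign)
  reported <- stats::setNames(as.integer(sizes) > min_report_size,
                              names(sizes))
  structure(
    list(assignment = best_assign,
         modularity_Q = best_q,
         removal_trace = data.frame(step = seq_along(trace_edge),
                                    edge = trace_edge, Q = trace_q,
                                    stringsAsFactors = FALSE),
         min_report_size = as.integer(min_report_size),
         reported = reported),
    class = "cluster_partition"
  )
}

#' @export
print.cluster_partition <- function(x, ...) {
  sizes <- sort(table(x$assignment), decreasing = TRUE)
  cat("Partition:", length(sizes), "clusters, Q =",
      format(x$modularity_Q, digits = 4), "\n")
  cat("  sizes:", paste(as.integer(sizes), collapse = ", "), "\n")
  cat("  reported (size >", x$min_report_size, "):",
      sum(x$reported), "cluster(s)\n")
  invisible(x)
}

#' Members of each cluster
#'
#' @param partition a `cluster_partition`.
#' @param reported_only keep only clusters above the reporting size.
#' @return named list of character vectors.
#' @export
cluster_members <- function(partition, reported_only = FALSE) {
  stopifnot(inherits(partition, "cluster_partition"))
  members <- split(names(partition$assignment), partition$assignment)
  if (reported_only) members <- members[partition$reported[names(members)]]
  lapply(members, sort)
}

#' Category enrichment per cluster
#'
#' For each (cluster, category) pair with at least one in-cluster hit,
#' computes the fold enrichment (in-cluster hit rate over network-wide hit
#' rate) and a one-sided hypergeometric upper-tail p-value. No multiplicity
#' correction is applied.
#'
#' @param net a `disease_network` with populated (non-`"Unknown"`-only)
#'   `node_category`.
#' @param partition a `cluster_partition` on `net`.
#' @param reported_only restrict to reported clusters (default TRUE).
#' @return data.frame `cluster`, `category`, `fold`, `p_value`,
#'   `cluster_hits`, `cluster_size`, `network_hits`, `network_size`, sorted
#'   by p ascending.
#' @export
category_enrichment <- function(net, partition, reported_only = TRUE) {
  stopifnot(inherits(net, "disease_network"),
            inherits(partition, "cluster_partition"))
  if (all(net$node_category == "Unknown")) {
    stop("node categories are unset; supply `node_category` when building ",
         "the network", call. = FALSE)
  }
  members <- cluster_members(partition, reported_only = reported_only)
  n_net <- length(net$nodes)
  rows <- list()
  for (cl in names(members)) {
    in_cl <- members[[cl]]
    cats <- unique(net$node_category[in_cl])
    for (cat in cats) {
      k <- sum(net$node_category[in_cl] == cat)
      K <- sum(net$node_category == cat)
      n_cl <- length(in_cl)
      rows[[length(rows) + 1L]] <- data.frame(
        cluster = cl, category = cat,
        fold = (k / n_cl) / (K / n_net),
        p_value = stats::phyper(k - 1L, K, n_net - K, n_cl,
                                lower.tail = FALSE),
        cluster_hits = k, cluster_size = n_cl,
        network_hits = K, network_size = n_net,
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$p_value), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write the partition and removal trace
#'
#' Writes `<dir>/partition.tsv` (`disease`, `cluster_id`) and
#' `<dir>/trace.tsv` (`step`, `edge`, `Q`).
#'
#' @param partition a `cluster_partition`.
#' @param dir output directory.
#' @export
write_partition <- function(partition, dir) {
  stopifnot(inherits(partition, "cluster_partition"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(
    data.frame(disease = names(partition$assignment),
               cluster_id = unname(partition$assignment)),
    file.path(dir, "partition.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE
  )
  utils::write.table(partition$removal_trace, file.path(dir, "trace.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
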